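wavelength,helix,coil,sheet
190,66893.5,-20134.1,21424.7
191,70919,-23319,26696.7
192,72158.3,-26503.4,31961.5
193,70403.1,-29552.3,36763.8
194,65770.6,-32321.6,40628.9
195,58671,-34669.7,43138.3
196,49721.6,-36469.9,44003.6
197,39632.2,-37621.4,43120.1
198,29089.4,-38059.5,40585.7
199,18668.3,-37761.7,36680.1
200,8788.2,-36750.1,31810.4
201,-289.2,-35088.9,26435.3
202,-8427.7,-32878.3,20988
203,-15569.4,-30244.7,15814.2
204,-21691.4,-27329.3,11135.8
205,-26779.1,-24275.5,7044.5
206,-30820.8,-21218.2,3520
207,-33820.1,-18274.5,465.8
208,-35817.4,-15537.3,-2249.6
209,-36909.4,-13072.5,-4753.2
210,-37257.3,-10918.7,-7137.7
211,-37078.7,-9089.8,-9442.3
212,-36623.9,-7579,-11648.5
213,-36141.5,-6364,-13686.2
214,-35840.7,-5412.1,-15450.1
215,-35859.9,-4685.3,-16822.3
216,-36246.7,-4144.4,-17696.6
217,-36954.5,-3751.6,-18000
218,-37854.9,-3473.2,-17708.6
219,-38762.3,-3280.2,-16853.4
220,-39466.4,-3148.8,-15517.1
221,-39766.3,-3060.2,-13822
222,-39500,-3000,-11911.5
223,-38565.5,-2957.7,-9931.3
224,-36931.8,-2925.8,-8011
225,-34638.5,-2899,-6251.9
226,-31786.2,-2873.8,-4720.4
227,-28520.1,-2847.9,-3448.2
228,-25009.5,-2819.9,-2436.9
229,-21428,-2789.1,-1666.2
230,-17935,-2754.9,-1102.2
231,-14662.8,-2717.2,-705.4
232,-11708.5,-2675.9,-436.8
233,-9131.3,-2631.2,-261.7
234,-6955,-2583.2,-151.7
235,-5173.7,-2532,-85
236,-3758.6,-2477.9,-46.1
237,-2666.7,-2421,-24.2
238,-1847.7,-2361.7,-12.3
239,-1250.4,-2300.2,-6
240,-826.3,-2236.7,-2.9
241,-533.3,-2171.4,-1.3
242,-336.2,-2104.7,-0.6
243,-206.9,-2036.8,-0.3
244,-124.4,-1967.9,-0.1
245,-73,-1898.4,0
246,-41.9,-1828.3,0
247,-23.4,-1758,0
248,-12.8,-1687.7,0
249,-6.8,-1617.7,0
250,-3.6,-1548,0
251,-1.8,-1479,0
252,-0.9,-1410.8,0
253,-0.4,-1343.7,0
254,-0.2,-1277.6,0
255,-0.1,-1212.9,0
256,0,-1149.6,0
257,0,-1087.8,0
258,0,-1027.8,0
259,0,-969.5,0
260,0,-913,0
261,0,-858.5,0
262,0,-805.9,0
263,0,-755.3,0
264,0,-706.8,0
265,0,-660.3,0
266,0,-615.9,0
267,0,-573.6,0
268,0,-533.3,0
269,0,-495.1,0
270,0,-458.9,0
271,0,-424.6,0
272,0,-392.3,0
273,0,-361.8,0
274,0,-333.2,0
275,0,-306.4,0
276,0,-281.2,0
277,0,-257.7,0
278,0,-235.8,0
279,0,-215.5,0
280,0,-196.5,0
281,0,-179,0
282,0,-162.7,0
283,0,-147.7,0
284,0,-133.9,0
285,0,-121.1,0
286,0,-109.4,0
287,0,-98.7,0
288,0,-88.9,0
289,0,-79.9,0
290,0,-71.7,0
291,0,-64.3,0
292,0,-57.5,0
293,0,-51.4,0
294,0,-45.8,0
295,0,-40.8,0
296,0,-36.3,0
297,0,-32.2,0
298,0,-28.5,0
299,0,-25.2,0
300,0,-22.3,0
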