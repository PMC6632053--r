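"name","label","series","notation","helicity_pct","ec50_uM","kd_nM","ratio_printed","parent_name"
"MP-292","","A","Ac-LTF[R8]EYWQL[Cba][S5]SAA-amide","32.8","0.54","18.6","29",""
"L1A","","A","Ac-ATF[R8]EYWQL[Cba][S5]SAA-amide","53.3","0.50","17.6","28","MP-292"
"T2A","","A","Ac-LAF[R8]EYWQL[Cba][S5]SAA-amide","36.2","1.0","21.3","47","MP-292"
"F3A","","A","Ac-LTA[R8]EYWQL[Cba][S5]SAA-amide","48.4","37","3600","10","MP-292"
"E5A","","A","Ac-LTF[R8]AYWQL[Cba][S5]SAA-amide","27.6","0.18","29.8","6","MP-292"
"Y6A","","A","Ac-LTF[R8]EAWQL[Cba][S5]SAA-amide","50.3","0.55","38.9","14","MP-292"
"W7A","","A","Ac-LTF[R8]EYAQL[Cba][S5]SAA-amide","ND","8.8","5093","2","MP-292"
"Q8A","","A","Ac-LTF[R8]EYWAL[Cba][S5]SAA-amide","33.4","0.10","26.5","4","MP-292"
"L9A","","A","Ac-LTF[R8]EYWQA[Cba][S5]SAA-amide","48.7","0.16","12.0","13","MP-292"
"Cba10A","","A","Ac-LTF[R8]EYWQLA[S5]SAA-amide","ND","11","176","61","MP-292"
"S12A","","A","Ac-LTF[R8]EYWQL[Cba][S5]AAA-amide","36.5","0.35","20.4","17","MP-292"
"L1(D-Leu)","","B","Ac-[D-Leu]TF[R8]EYWQL[Cba][S5]SAA-amide","44.1","0.6","31","18","MP-292"
"T2(D-Thr)","","B","Ac-L[D-Thr]F[R8]EYWQL[Cba][S5]SAA-amide","40.7","3.4","136","25","MP-292"
"F3(D-Phe)","","B","Ac-LT[D-Phe][R8]EYWQL[Cba][S5]SAA-amide","51.8",">50","6485",">8","MP-292"
"E5(D-Glu)","","B","Ac-LTF[R8][D-Glu]YWQL[Cba][S5]SAA-amide","38.2","1.0","32","30","MP-292"
"Y6(D-Tyr)","","B","Ac-LTF[R8]E[D-Tyr]WQL[Cba][S5]SAA-amide","43.2","3.2","286","11","MP-292"
"MP-384","W6(D-Trp)","B","Ac-LTF[R8]EY[D-Trp]QL[Cba][S5]SAA-amide","41.0","0.6","30","20","MP-292"
"Q8(D-Gln)","","B","Ac-LTF[R8]EYW[D-Gln]L[Cba][S5]SAA-amide","27.1","2.1","22","95","MP-292"
"L9(D-Leu)","","B","Ac-LTF[R8]EYWQ[D-Leu][Cba][S5]SAA-amide","39.0","1.1","30","37","MP-292"
"Cba10(D-Cba)","","B","Ac-LTF[R8]EYWQL[D-Cba][S5]SAA-amide","ND","8.1","1650","5","MP-292"
"S12(D-Ser)","","B","Ac-LTF[R8]EYWQL[Cba][S5][D-Ser]AA-amide","41.2","1.2","8.6","140","MP-292"
"A13(D-Ala)","","B","Ac-LTF[R8]EYWQL[Cba][S5]S[D-Ala]A-amide","41.8","0.6","17","35","MP-292"
"A14(D-Ala)","","B","Ac-LTF[R8]EYWQL[Cba][S5]SA[D-Ala]-amide","34.6","0.5","18","28","MP-292"
"MP-189","Linear Parent","C","Ac-LTF[Aib]EYWQL[Cba][Aib]SAA-amide","35.3","33.5","43.1","777",""
"Linear L1(D-Leu)","L1(D-Leu)","C","Ac-[D-Leu]TF[Aib]EYWQL[Cba][Aib]SAA-amide","37.2",">50","277",">180","MP-189"
"Linear E5(D-Glu)","E5(D-Glu)","C","Ac-LTF[Aib][D-Glu]YWQL[Cba][Aib]SAA-amide","21.4",">50","135",">370","MP-189"
"Linear Q8(D-Gln)","Q8(D-Gln)","C","Ac-LTF[Aib]EYW[D-Gln]L[Cba][Aib]SAA-amide","21.8",">50","119",">370","MP-189"
"Linear L9(D-Leu)","L9(D-Leu)","C","Ac-LTF[Aib]EYWQ[D-Leu][Cba][Aib]SAA-amide","19.7",">50","88",">568","MP-189"
"MP-081","","table2","Ac-K(N3)-(βA)-LTF[R8]EYWAQ[Cba][S5]SAA-amide","49.6","0.42","19.0","22",""
"L1(Aib)","L1(Aib)","table2","Ac-K(N3)-(βA)-[Aib]TF[R8]EYWAQ[Cba][S5]SAA-amide","42.7","0.49","29.5","17","MP-081"
"T2(Aib)","T2(Aib)","table2","Ac-K(N3)-(βA)-L[Aib]F[R8]EYWAQ[Cba][S5]SAA-amide","38.3","2.9","1706","2","MP-081"
"A8(Aib)","A8(Aib)","table2","Ac-K(N3)-(βA)-LTF[R8]EYW[Aib]Q[Cba][S5]SAA-amide","37.5","1.5","119.4","12","MP-081"
"Q9(Aib)","Q9(Aib)","table2","Ac-K(N3)-(βA)-LTF[R8]EYWA[Aib][Cba][S5]SAA-amide","28","0.25","33.1","8","MP-081"
"S12(Aib)","S12(Aib)","table2","Ac-K(N3)-(βA)-LTF[R8]EYWAQ[Cba][S5][Aib]AA-amide","37.3","0.25","24.4","10","MP-081"
"A13(Aib)","A13(Aib)","table2","Ac-K(N3)-(βA)-LTF[R8]EYWAQ[Cba][S5]S[Aib]A-amide","34.4","0.59","25.7","23","MP-081"
"L1(NMe-Leu)","L1(N-methyl L-Leu)","table2","Ac-K(N3)-(βA)-[NMe-L]TF[R8]EYWAQ[Cba][S5]SAA-amide","32.6","0.46","23.5","20","MP-081"
"L1(NMe-Ala)","L1(N-methyl L-Ala)","table2","Ac-K(N3)-(βA)-[NMe-A]TF[R8]EYWAQ[Cba][S5]SAA-amide","47.2","1.49","15.4","97","MP-081"
"T2(NMe-Thr)","T2(N-methyl L-Thr)","table2","Ac-K(N3)-(βA)-L[NMe-T]F[R8]EYWAQ[Cba][S5]SAA-amide","38.2","7.7","352.2","22","MP-081"
"A8(NMe-Ala)","A8(N-methyl L-Ala)","table2","Ac-K(N3)-(βA)-LTF[R8]EYW[NMe-A]Q[Cba][S5]SAA-amide","16.9",">50","671.3",">75","MP-081"
"Q9(NMe-Gln)","Q9(N-methyl L-Gln)","table2","Ac-K(N3)-(βA)-LTF[R8]EYWA[NMe-Q][Cba][S5]SAA-amide","20.2",">50","211.2",">237","MP-081"
"A13(NMe-Ala)","A13(N-methyl L-Ala)","table2","Ac-K(N3)-(βA)-LTF[R8]EYWAQ[Cba][S5]S[NMe-A]A-amide","38.6","1.6","10.0","158","MP-081"
"A14(NMe-Ala)","A14(N-methyl L-Ala)","table2","Ac-K(N3)-(βA)-LTF[R8]EYWAQ[Cba][S5]SA[NMe-A]-amide","47.5","0.71","5.9","120","MP-081"
"L1P","L1P","table2","Ac-K(N3)-(βA)-PTF[R8]EYWAQ[Cba][S5]SAA-amide","41.6","0.75","21.9","34","MP-081"
"Q9P","Q9P","table2","Ac-K(N3)-(βA)-LTF[R8]EYWAP[Cba][S5]SAA-amide","27.4","3.1","77.1","41","MP-081"
"S12P","S12P","table2","Ac-K(N3)-(βA)-LTF[R8]EYWAQ[Cba][S5]PAA-amide","30.8","3.7","45.7","80","MP-081"
"L1G","L1G","table2","Ac-K(N3)-(βA)-GTF[R8]EYWAQ[Cba][S5]SAA-amide","44.6","1.6","22.1","73","MP-081"
"E5G","E5G","table2","Ac-K(N3)-(βA)-LTF[R8]GYWAQ[Cba][S5]SAA-amide","28.6","0.26","61.8","4","MP-081"
"Q9G","Q9G","table2","Ac-K(N3)-(βA)-LTF[R8]EYWAG[Cba][S5]SAA-amide","38.8","0.68","42.0","16","MP-081"
"S12G","S12G","table2","Ac-K(N3)-(βA)-LTF[R8]EYWAQ[Cba][S5]GAA-amide","46.5","0.65","18.9","34","MP-081"
"L1G,E5G,A8G","L1G,E5G,A8G","table2","Ac-K(N3)-(βA)-GTF[R8]GYWGQ[Cba][S5]SAA-amide","20.4","1.7","49.8","34","MP-081"
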