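# Independent brute-force oracles. These share no code with the package
# solvers: plain bisection on the mass-balance equations.

# bound tracer fraction for single-ligand binding: bisection on bound b
frac_direct_bisect <- function(kd, lt, pt) {
  g <- function(b) kd * b - (lt - b) * (pt - b)
  lo <- 0
  hi <- min(lt, pt)
  if (hi == 0) return(0)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  ((lo + hi) / 2) / lt
}

# free protein for two competing ligands: bisection on p
free_protein_bisect <- function(kd1, kd2, lst, lt, pt) {
  g <- function(p) p + lst * p / (p + kd1) + lt * p / (p + kd2) - pt
  lo <- 0
  hi <- pt
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

frac_comp_bisect <- function(kd1, kd2, lst, lt, pt) {
  p <- free_protein_bisect(kd1, kd2, lst, lt, pt)
  p / (p + kd1)
}
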