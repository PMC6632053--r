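# Golden values below were frozen from the independent bisection oracles in
# helper-oracles.R before the closed forms were written.

test_that("direct 1:1 bound fraction matches limits and the bisection oracle", {
  expect_equal(frac_bound_direct(13.0, 50, 0), 0)
  expect_equal(frac_bound_direct(0, 50, 250), 1)
  # assay constants: tracer Kd 13.0 nM, 50 nM tracer, 250 nM protein
  expect_equal(frac_bound_direct(13.0, 50, 250), 0.9398173592,
               tolerance = 1e-9)
  expect_error(frac_bound_direct(13.0, 0, 250), "lt")
  # oracle agreement across regimes
  for (kd in c(0.1, 13, 1e3, 1e5)) {
    for (pt in c(1, 50, 250, 1e4)) {
      expect_equal(frac_bound_direct(kd, 50, pt),
                   frac_direct_bisect(kd, 50, pt), tolerance = 1e-9)
    }
  }
})

test_that("direct anisotropy is the linear map of the bound fraction", {
  expect_equal(anisotropy_direct(0.05, 0.25, 13.0, 50, 0), 0.05)
  expect_equal(anisotropy_direct(0.05, 0.25, 0, 50, 250), 0.25)
  expect_equal(anisotropy_direct(0.05, 0.25, 13.0, 50, 250), 0.2379634718,
               tolerance = 1e-8)
  expect_warning(anisotropy_direct(0.25, 0.05, 13, 50, 250), "rb < r0")
})

test_that("competition closed form reduces to the direct model and its limits", {
  direct <- frac_bound_direct(13.0, 50, 250)
  expect_equal(frac_bound_competition(13.0, 18.6, 50, 0, 250), direct,
               tolerance = 1e-12)
  expect_equal(frac_bound_competition(13.0, 1e12, 50, 5000, 250), direct,
               tolerance = 1e-6)
  # golden value frozen from the bisection oracle (Kd2 = 18.6 nM competitor
  # at 500 nM against the standard assay)
  expect_equal(frac_bound_competition(13.0, 18.6, 50, 500, 250),
               0.510697503057, tolerance = 1e-9)
  # agrees with the package's own numerical solver too
  nm <- solve_equilibrium_numeric(13.0, 18.6, 50, 500, 250)
  expect_equal(frac_bound_competition(13.0, 18.6, 50, 500, 250),
               nm[["bound_tracer"]] / 50, tolerance = 1e-9)
  expect_warning(frac_bound_competition(13.0, 18.6, 50, 100, 40),
                 "validity")
})

test_that("competition anisotropy reduces and displaces correctly", {
  expect_equal(anisotropy_competition(0.05, 0.25, 13.0, 18.6, 50, 0, 250),
               anisotropy_direct(0.05, 0.25, 13.0, 50, 250))
  # full displacement limit
  expect_equal(anisotropy_competition(0.05, 0.25, 13.0, 1.0, 50, 1e9, 250),
               0.05, tolerance = 1e-4)
  # linear map: midpoint fraction by construction
  f <- frac_bound_competition(13.0, 18.6, 50, 500, 250)
  expect_equal(anisotropy_competition(0, 1, 13.0, 18.6, 50, 500, 250), f)
})

test_that("numerical equilibrium solver conserves mass and handles edge cases", {
  expect_equal(solve_equilibrium_numeric(13, 18.6, 50, 500, 0),
               c(bound_tracer = 0, bound_competitor = 0))
  # symmetry: identical ligands bind identically
  s <- solve_equilibrium_numeric(20, 20, 100, 100, 250)
  expect_equal(s[["bound_tracer"]], s[["bound_competitor"]],
               tolerance = 1e-9)
  # no competitor reduces to the quadratic solution
  s0 <- solve_equilibrium_numeric(13, 18.6, 50, 0, 250)
  expect_equal(s0[["bound_tracer"]] / 50, frac_direct_bisect(13, 50, 250),
               tolerance = 1e-9)
})

test_that("closed form agrees with the oracle and behaves monotonically over random draws", {
  set.seed(42)
  n <- 2000
  kd1 <- 10^runif(n, -1, 6)
  kd2 <- 10^runif(n, -1, 6)
  lst <- 10^runif(n, 0, 5)
  pt <- lst + 10^runif(n, 0, 5)
  lt <- 10^runif(n, 0, 5)
  for (i in seq_len(n)) {
    cf <- frac_bound_competition(kd1[i], kd2[i], lst[i], lt[i], pt[i])
    nm <- solve_equilibrium_numeric(kd1[i], kd2[i], lst[i], lt[i], pt[i])
    fr <- nm[["bound_tracer"]] / lst[i]
    expect_lt(abs(cf - fr), 1e-6 * max(fr, 1e-12))
    # conservation
    expect_lte(nm[["bound_tracer"]], lst[i] * (1 + 1e-9))
    expect_lte(nm[["bound_competitor"]], lt[i] * (1 + 1e-9))
    expect_lte(sum(nm), pt[i] * (1 + 1e-9))
  }
  # pairwise monotonicity on a subset of the same draws
  for (i in seq_len(200)) {
    base <- frac_bound_competition(kd1[i], kd2[i], lst[i], lt[i], pt[i])
    expect_lte(frac_bound_competition(kd1[i], kd2[i], lst[i], 2 * lt[i],
                                      pt[i]), base + 1e-12)
    expect_lte(frac_bound_competition(2 * kd1[i], kd2[i], lst[i], lt[i],
                                      pt[i]), base + 1e-12)
    expect_gte(frac_bound_competition(kd1[i], 2 * kd2[i], lst[i], lt[i],
                                      pt[i]), base - 1e-12)
    expect_gte(frac_bound_competition(kd1[i], kd2[i], lst[i], lt[i],
                                      2 * pt[i]), base - 1e-12)
  }
})

test_that("direct fit round-trips noiseless curves for varied truths", {
  for (kd_true in c(1, 13, 500)) {
    cur <- gen_direct_titration(kd = kd_true, r0 = 0.05, rb = 0.25,
                                noise_sd = 0, seed = 1)
    f <- fit_direct(cur, lt = 50)
    expect_true(f$converged)
    expect_equal(f$estimates[["Kd"]], kd_true, tolerance = 1e-6)
    expect_equal(f$estimates[["r0"]], 0.05, tolerance = 1e-6)
    expect_equal(f$estimates[["rb"]], 0.25, tolerance = 1e-6)
  }
  # fixing the anchors still recovers Kd
  cur <- gen_direct_titration(kd = 13, noise_sd = 0, seed = 1)
  ff <- fit_direct(cur, lt = 50, fixed = list(r0 = 0.05, rb = 0.25))
  expect_equal(ff$estimates[["Kd"]], 13, tolerance = 1e-6)
})

test_that("degenerate direct curves report non-convergence, never an error", {
  flat <- data.frame(x = c(0, 1, 10, 100, 1000), r = rep(0.1, 5))
  f <- fit_direct(flat, lt = 50)
  expect_false(f$converged)
  short <- data.frame(x = c(0, 10, 100), r = c(0.05, 0.1, 0.2))
  expect_false(fit_direct(short, lt = 50)$converged)
})

test_that("competition fit round-trips noiseless curves, tight and weak binders", {
  for (kd2_true in c(18.6, 3600)) {
    cur <- gen_competition_titration(kd2 = kd2_true, noise_sd = 0, seed = 1)
    f <- fit_competition(cur)
    expect_true(f$converged)
    expect_equal(f$estimates[["Kd2"]], kd2_true, tolerance = 1e-6)
  }
  expect_error(fit_competition(data.frame(x = 1:6, r = 1:6 / 10),
                               pt = 40, lst = 50), "pt > lst")
})

test_that("competition fit flags a baseline below the free-tracer anisotropy", {
  # construct a curve whose displacement floor undershoots the free tracer
  lt <- c(0, 10^seq(1, log10(5e4), length.out = 11))
  r <- anisotropy_competition(0.03, 0.25, 13, 20, 50, lt, 250)
  f <- fit_competition(data.frame(x = lt, r = r), r_free = 0.05)
  expect_true(f$diagnostics$baseline_below_free)
  # and a clean curve does not
  r2 <- anisotropy_competition(0.05, 0.25, 13, 20, 50, lt, 250)
  f2 <- fit_competition(data.frame(x = lt, r = r2), r_free = 0.049)
  expect_false(f2$diagnostics$baseline_below_free)
})

test_that("titration CSVs round-trip through read_titration", {
  path <- withr::local_tempfile(fileext = ".csv")
  cur <- gen_direct_titration(noise_sd = 0)
  write.csv(data.frame(conc_nM = cur$x, anisotropy = cur$r,
                       replicate = cur$replicate), path, row.names = FALSE)
  back <- read_titration(path)
  expect_equal(back$x, cur$x)
  expect_equal(back$r, cur$r)
  expect_error(read_titration(textConnection("a,b\n1,2")), "conc_nM")
})
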