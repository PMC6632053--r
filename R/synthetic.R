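# Synthetic-data generators with known ground truth for every input class:
# anisotropy titrations, dose-response curves, CD spectra with a planted
# helix fraction, stability decays, and whole library tables carrying a
# planted lipophilicity law.
#
# Determinism contract: every generator is bit-reproducible under a fixed
# seed. A global seed is mapped to per-object substreams through
# derive_seed(), so adding one generator call never shifts the stream of
# another.

#' Derive a deterministic substream seed
#'
#' Maps a global seed and a character key to an integer seed below 2^31, so
#' independent generated objects draw from decoupled streams.
#'
#' @param seed Integer global seed.
#' @param key Character stream key (e.g. the generated object's name).
#' @return Integer seed.
#' @export
derive_seed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)) * 2654435761) %% 2147483647
  as.integer((abs(seed) * 1000003 + h) %% 2147483647)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a direct 1:1 anisotropy titration
#'
#' Protein is titrated against a fixed labeled tracer; anisotropy follows
#' [anisotropy_direct()] plus Gaussian noise. The default grid and constants
#' mirror the Mdm2 FP assay: tracer at 50 nM, protein titrated through the
#' Kd region, triplicate measurement.
#'
#' @param kd True dissociation constant (nM); default 13.0, the tracer Kd.
#' @param r0,rb True free and bound anisotropies.
#' @param lt Tracer concentration (nM).
#' @param pt_grid Protein concentrations (nM); default 0 plus 11 log-spaced
#'   points over 1-2000 nM.
#' @param replicates Replicates per concentration (default 3).
#' @param noise_sd Gaussian anisotropy noise SD (default 0.005).
#' @param seed Integer seed.
#' @return Data frame (`x`, `r`, `replicate`) with the truth parameters and
#'   seed attached as the `"truth"` attribute.
#' @export
gen_direct_titration <- function(kd = 13.0, r0 = 0.05, rb = 0.25, lt = 50,
                                 pt_grid = c(0, 10^seq(0, log10(2000),
                                                       length.out = 11)),
                                 replicates = 3, noise_sd = 0.005,
                                 seed = 1) {
  stopifnot(noise_sd >= 0, replicates >= 1)
  x <- rep(pt_grid, times = replicates)
  mu <- anisotropy_direct(r0, rb, kd, lt, x)
  r <- .with_seed(seed, mu + stats::rnorm(length(x), 0, noise_sd))
  out <- data.frame(x = x, r = r,
                    replicate = rep(seq_len(replicates),
                                    each = length(pt_grid)))
  attr(out, "truth") <- list(kd = kd, r0 = r0, rb = rb, lt = lt,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Simulate a competitive displacement titration
#'
#' An unlabeled competitor is titrated against the preformed protein-tracer
#' complex at the assay constants (`kd1` = 13.0 nM, `lst` = 50 nM,
#' `pt` = 250 nM).
#'
#' @param kd2 True competitor dissociation constant (nM).
#' @param kd1,lst,pt Assay constants.
#' @param lt_grid Competitor concentrations (nM); default 0 plus 11
#'   log-spaced points over 10 nM - 50 uM.
#' @inheritParams gen_direct_titration
#' @return Data frame (`x`, `r`, `replicate`) with a `"truth"` attribute.
#' @export
gen_competition_titration <- function(kd2 = 18.6, kd1 = 13.0, lst = 50,
                                      pt = 250,
                                      lt_grid = c(0, 10^seq(1, log10(5e4),
                                                            length.out = 11)),
                                      replicates = 3, r0 = 0.05, rb = 0.25,
                                      noise_sd = 0.005, seed = 1) {
  stopifnot(noise_sd >= 0, replicates >= 1)
  x <- rep(lt_grid, times = replicates)
  mu <- anisotropy_competition(r0, rb, kd1, kd2, lst, x, pt)
  r <- .with_seed(seed, mu + stats::rnorm(length(x), 0, noise_sd))
  out <- data.frame(x = x, r = r,
                    replicate = rep(seq_len(replicates),
                                    each = length(lt_grid)))
  attr(out, "truth") <- list(kd2 = kd2, kd1 = kd1, lst = lst, pt = pt,
                             r0 = r0, rb = rb, noise_sd = noise_sd,
                             seed = seed)
  out
}

#' Simulate a normalized dose-response curve
#'
#' Four-parameter logistic truth plus Gaussian noise on the percent scale.
#' A truth EC50 above the highest dose generates the censoring scenario.
#'
#' @param ec50 True EC50 (uM).
#' @param hill True hill slope.
#' @param top,bottom True asymptotes (percent of max control).
#' @param dose_grid Doses (uM); default 10 log-spaced points over
#'   0.01-50 uM.
#' @param noise_sd Gaussian noise SD in percent (default 5).
#' @param seed Integer seed.
#' @return Data frame (`dose`, `response`) with a `"truth"` attribute.
#' @export
gen_dose_response <- function(ec50 = 0.54, hill = 1.5, top = 100,
                              bottom = 0,
                              dose_grid = 10^seq(-2, log10(50),
                                                 length.out = 10),
                              noise_sd = 5, seed = 1) {
  stopifnot(noise_sd >= 0)
  mu <- .logistic4(dose_grid, bottom, top, log10(ec50), hill)
  y <- .with_seed(seed, mu + stats::rnorm(length(mu), 0, noise_sd))
  out <- data.frame(dose = dose_grid, response = y)
  attr(out, "truth") <- list(ec50 = ec50, hill = hill, top = top,
                             bottom = bottom, noise_sd = noise_sd,
                             seed = seed)
  out
}

#' Simulate a CD spectrum with a planted helix fraction
#'
#' The mean-residue-ellipticity curve is
#' `f (1 - k/n) helix(lambda) + (1 - f) coil(lambda)` over the packaged
#' reference shapes, back-converted to raw millidegrees at the stated
#' concentration / path length / residue count, plus optional noise. The
#' defaults mirror the CD protocol: 1 mM peptide, 0.2 cm path, 190-300 nm.
#'
#' @param fraction_helix Planted helix fraction in `[0, 1]`.
#' @param n_residues Residue count (default 14, the stapled template).
#' @param conc Molar concentration (default 1e-3).
#' @param pathlength Path length in cm (default 0.2).
#' @param noise_sd Gaussian noise on raw millidegrees (default 0).
#' @param constants [helix_constants()] for the length correction.
#' @param seed Integer seed.
#' @return A [cd_spectrum()] with a `"truth"` attribute.
#' @export
gen_cd_spectrum <- function(fraction_helix, n_residues = 14, conc = 1e-3,
                            pathlength = 0.2, noise_sd = 0,
                            constants = helix_constants(), seed = 1) {
  stopifnot(fraction_helix >= 0, fraction_helix <= 1, noise_sd >= 0)
  basis <- cd_reference_basis()
  len_corr <- 1 - constants$k / n_residues
  mre <- fraction_helix * len_corr * basis$helix +
    (1 - fraction_helix) * basis$coil
  mdeg <- mre * 10 * conc * pathlength * n_residues
  if (noise_sd > 0) {
    mdeg <- .with_seed(seed, mdeg + stats::rnorm(length(mdeg), 0, noise_sd))
  }
  s <- cd_spectrum(basis$wavelength, mdeg, conc, pathlength, n_residues)
  attr(s, "truth") <- list(fraction_helix = fraction_helix,
                           n_residues = n_residues, noise_sd = noise_sd,
                           seed = seed)
  s
}

# random parseable variants of the stapled template, for synthetic libraries
.syn_notation <- function(i, rng_letters) {
  core <- c("L", "T", "F", "R8", "E", "Y", "W", "Q", "L", "Cba", "S5",
            "S", "A", "A")
  pos <- sample(c(1:3, 5:10, 12:14), 1)
  core[pos] <- rng_letters[sample(length(rng_letters), 1)]
  tok <- vapply(core, function(cd) {
    if (nchar(cd) == 1) cd else paste0("[", cd, "]")
  }, "")
  paste0("Ac-", paste(tok, collapse = ""), "-amide")
}

#' Simulate a peptide library with a planted lipophilicity law
#'
#' Generates `n_peptides` rows under the law
#' \deqn{\log_{10}(ratio) = a + b \cdot logD + \epsilon, \quad
#'       \epsilon \sim N(0, \sigma^2)}
#' with logD drawn from `N(logd_mean, logd_sd^2)` and Kd log-uniform over
#' `kd_range`; EC50s are back-solved as `ratio * kd / 1000` so the planted
#' relationship survives the full ratio recomputation. EC50s above
#' `max_dose` become censored `">max_dose"` rows and a fraction `nd_rate` of
#' helicity entries is replaced by "ND". The default law slope is negative
#' (more lipophilic peptides are more permeable, hence lower cell/target
#' ratios) with `b^2 logd_sd^2 / (b^2 logd_sd^2 + sigma^2) = 0.5`, the
#' strength of the observed library correlation; the default `kd_range`
#' spans the printed library's 5-5000 nM.
#'
#' @param n_peptides Number of rows (`>= 3`), default 50 (the study library).
#' @param a,b Intercept and slope of the planted law.
#' @param sigma Residual SD of the law (log10 units).
#' @param logd_mean,logd_sd LogD distribution parameters.
#' @param kd_range Kd range (nM) for the log-uniform draw.
#' @param max_dose Censoring bound for EC50 (uM).
#' @param nd_rate Fraction of helicity entries replaced by "ND".
#' @param seed Integer seed.
#' @return A `library_table` with the planted parameters in the `"truth"`
#'   attribute (including `expected_r_squared` for the log10-ratio
#'   regression before censoring).
#' @export
gen_library <- function(n_peptides = 50, a = 3.0, b = -0.6, sigma = 0.6,
                        logd_mean = 2.5, logd_sd = 1.0,
                        kd_range = c(5, 5000), max_dose = 50,
                        nd_rate = 0.06, seed = 1) {
  stopifnot(n_peptides >= 3, sigma >= 0, is.finite(b))
  .with_seed(derive_seed(seed, "library"), {
    logd <- stats::rnorm(n_peptides, logd_mean, logd_sd)
    eps <- stats::rnorm(n_peptides, 0, sigma)
    ratio <- 10^(a + b * logd + eps)
    kd <- 10^stats::runif(n_peptides, log10(kd_range[1]),
                          log10(kd_range[2]))
    ec50 <- ratio * kd / 1000
    hel <- pmin(pmax(stats::rnorm(n_peptides, 40, 8), 5), 95)
    nd <- stats::runif(n_peptides) < nd_rate
    notation <- vapply(seq_len(n_peptides), .syn_notation, "",
                       rng_letters = c("A", "G", "S", "N", "K", "V"))
    d <- data.frame(
      name = sprintf("SYN-%03d", seq_len(n_peptides)),
      label = "", series = "synthetic", notation = notation,
      helicity_pct = ifelse(nd, "ND", format(round(hel, 1))),
      ec50_uM = ifelse(ec50 > max_dose, paste0(">", max_dose),
                       format(ec50, digits = 6)),
      kd_nM = kd, logd = logd, parent_name = "",
      stringsAsFactors = FALSE)
    out <- as_library_table(d)
    attr(out, "truth") <- list(
      a = a, b = b, sigma = sigma, logd_mean = logd_mean,
      logd_sd = logd_sd, seed = seed,
      expected_r_squared = if (sigma == 0 && b != 0) 1 else {
        (b^2 * logd_sd^2) / (b^2 * logd_sd^2 + sigma^2)
      })
    out
  })
}
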