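# Circular-dichroism analysis: conversion of raw ellipticity to mean residue
# ellipticity (MRE) and estimation of fractional alpha-helicity.
#
# Two transparent estimators are provided in place of proprietary
# neural-network deconvolution: a single-wavelength 222 nm estimator with
# length-corrected helix limits, and a constrained basis fit against
# packaged helix/coil/sheet reference shapes.

#' Construct a CD spectrum object
#'
#' @param wavelength Wavelengths in nm, strictly monotone (typically
#'   190-300).
#' @param ellipticity Raw ellipticity in millidegrees, same length.
#' @param conc Molar peptide concentration (M), `> 0`.
#' @param pathlength Cuvette path length (cm), `> 0`.
#' @param n_residues Number of residues used for the per-residue
#'   normalization, `>= 2`.
#' @return An object of class `cd_spectrum` (a data frame with metadata
#'   attributes).
#' @export
cd_spectrum <- function(wavelength, ellipticity, conc, pathlength,
                        n_residues) {
  stopifnot(length(wavelength) == length(ellipticity))
  if (!(conc > 0) || !(pathlength > 0)) {
    stop("conc and pathlength must be > 0", call. = FALSE)
  }
  if (n_residues < 2) stop("n_residues must be >= 2", call. = FALSE)
  d <- diff(wavelength)
  if (!(all(d > 0) || all(d < 0))) {
    stop("wavelengths must be strictly monotone", call. = FALSE)
  }
  structure(data.frame(wavelength = wavelength, ellipticity = ellipticity),
            conc = conc, pathlength = pathlength,
            n_residues = as.integer(n_residues),
            class = c("cd_spectrum", "data.frame"))
}

#' Convert raw ellipticity to mean residue ellipticity
#'
#' \deqn{[\theta]_{MRE}(\lambda) = \theta_{mdeg}(\lambda) /
#'       (10 \, c_M \, \ell_{cm} \, n_{res})}
#' in deg cm^2 dmol^-1 per residue.
#'
#' @param s A [cd_spectrum()].
#' @return An object of class `mre_spectrum`: data frame with `wavelength`
#'   and `mre`, carrying `n_residues` as an attribute.
#' @examples
#' s <- cd_spectrum(220:224, rep(-20, 5), conc = 1e-3, pathlength = 0.2,
#'                  n_residues = 14)
#' ellipticity_to_mre(s)$mre[1]  # -20 / (10 * 0.001 * 0.2 * 14) = -714.3
#' @export
ellipticity_to_mre <- function(s) {
  stopifnot(inherits(s, "cd_spectrum"))
  denom <- 10 * attr(s, "conc") * attr(s, "pathlength") * attr(s, "n_residues")
  structure(data.frame(wavelength = s$wavelength, mre = s$ellipticity / denom),
            n_residues = attr(s, "n_residues"),
            class = c("mre_spectrum", "data.frame"))
}

#' Helix/coil limiting constants for the 222 nm estimator
#'
#' Field-standard limiting mean-residue-ellipticity values: an infinite helix
#' at `theta_helix_inf` with the finite-length correction `(1 - k/n)`, and a
#' coil baseline `theta_coil` (all deg cm^2 dmol^-1).
#'
#' @param theta_helix_inf Infinite-helix MRE at 222 nm (default -39500).
#' @param k Finite-length correction constant (default 2.57).
#' @param theta_coil Random-coil MRE at 222 nm (default -3000).
#' @return A named list of the three constants.
#' @export
helix_constants <- function(theta_helix_inf = -39500, k = 2.57,
                            theta_coil = -3000) {
  list(theta_helix_inf = theta_helix_inf, k = k, theta_coil = theta_coil)
}

.helicity_estimate <- function(fraction, method, mre_222 = NA_real_) {
  clipped <- fraction < 0 || fraction > 1
  structure(list(fraction_helix = min(max(fraction, 0), 1),
                 raw_fraction = fraction, method = method,
                 mre_222 = mre_222, out_of_range = clipped),
            class = "helicity_estimate")
}

#' @export
print.helicity_estimate <- function(x, ...) {
  cat(sprintf("Helix fraction: %.3f  (%s%s)\n", x$fraction_helix, x$method,
              if (x$out_of_range) {
                sprintf(", clipped from %.3f", x$raw_fraction)
              } else ""))
  invisible(x)
}

# nearest grid point to 222 nm, tolerance 1 nm
.mre_at_222 <- function(m) {
  i <- which.min(abs(m$wavelength - 222))
  if (abs(m$wavelength[i] - 222) > 1) {
    stop("222 nm not covered by the spectrum (tolerance 1 nm)",
         call. = FALSE)
  }
  m$mre[i]
}

#' Single-wavelength (222 nm) helicity estimator
#'
#' \deqn{f_H = ([\theta]_{222} - \theta_{coil}) /
#'       (\theta_{helix}^\infty (1 - k/n) - \theta_{coil})}
#' Out-of-range fractions are clipped to `[0, 1]` with the raw value
#' preserved on the result.
#'
#' @param m An `mre_spectrum` covering 222 nm (nearest point within 1 nm).
#' @param n_residues Residue count for the length correction; defaults to
#'   the `n_residues` attribute carried by `m` (cap-exclusive count).
#' @param constants A [helix_constants()] list.
#' @return A `helicity_estimate` with fields `fraction_helix`, `method`,
#'   `mre_222`, `raw_fraction`, `out_of_range`.
#' @export
helicity_single_wavelength <- function(m, n_residues = attr(m, "n_residues"),
                                       constants = helix_constants()) {
  stopifnot(inherits(m, "mre_spectrum"), !is.null(n_residues))
  mre222 <- .mre_at_222(m)
  denom <- constants$theta_helix_inf * (1 - constants$k / n_residues) -
    constants$theta_coil
  .helicity_estimate((mre222 - constants$theta_coil) / denom,
                     "single_wavelength_222", mre222)
}

#' Packaged reference CD basis shapes
#'
#' Synthetic helix / coil / sheet mean-residue-ellipticity shapes (190-300 nm,
#' 1 nm step) parameterized from the canonical band structure of each
#' secondary-structure class: helix with the 208/222 nm double minimum and
#' positive ~192 nm band (scaled to -39500 at 222 nm for an infinite helix),
#' coil with its deep ~198 nm minimum (-3000 at 222 nm), sheet with the
#' ~217 nm minimum and positive ~196 nm band.
#'
#' @return Data frame with columns `wavelength`, `helix`, `coil`, `sheet`.
#' @export
cd_reference_basis <- function() {
  path <- system.file("extdata", "cd_reference_basis.csv",
                      package = "helixscan")
  if (!nzchar(path)) stop("packaged CD basis not found", call. = FALSE)
  utils::read.csv(path)
}

# Exact active-set solver for min ||B c - y|| s.t. sum(c) = 1, c >= 0.
# The equality constraint is eliminated by substitution (last active
# coefficient = 1 - sum of the others), leaving an ordinary least-squares
# problem; negative coefficients are dropped from the active set until the
# solution is feasible. Exact for the small (<= 3 column) bases used here.
.simplex_ls <- function(B, y) {
  k <- ncol(B)
  sc <- max(abs(B))
  if (sc == 0 || qr(B / sc)$rank < k) {
    stop("rank-deficient basis", call. = FALSE)
  }
  Bs <- B / sc
  ys <- y / sc
  active <- seq_len(k)
  repeat {
    ka <- length(active)
    if (ka == 1) {
      c_full <- numeric(k)
      c_full[active] <- 1
      return(c_full)
    }
    piv <- active[ka]
    others <- active[-ka]
    X <- Bs[, others, drop = FALSE] - Bs[, piv]
    beta <- qr.coef(qr(X), ys - Bs[, piv])
    ca <- c(beta, 1 - sum(beta))  # order: others, pivot
    if (anyNA(ca)) stop("degenerate basis system", call. = FALSE)
    if (all(ca >= -1e-10)) {
      c_full <- numeric(k)
      c_full[c(others, piv)] <- pmax(ca, 0)
      return(c_full / sum(c_full))
    }
    active <- c(others, piv)[-which.min(ca)]
  }
}

#' Basis-fit helicity estimator
#'
#' Fits the MRE spectrum as a non-negative combination of helix, coil and
#' sheet reference shapes constrained to sum to one, and reports the helix
#' coefficient. The helix basis is length-corrected by `(1 - k/n)` so the
#' coefficient is directly comparable to the single-wavelength estimator.
#'
#' @inheritParams helicity_single_wavelength
#' @param basis Reference shapes as returned by [cd_reference_basis()]; must
#'   cover the spectrum's wavelength range.
#' @return A `helicity_estimate` with `method = "basis_nnls"` and the full
#'   coefficient vector in `$coefficients`.
#' @export
helicity_basis_fit <- function(m, basis = cd_reference_basis(),
                               n_residues = attr(m, "n_residues"),
                               constants = helix_constants()) {
  stopifnot(inherits(m, "mre_spectrum"), !is.null(n_residues))
  if (min(m$wavelength) < min(basis$wavelength) ||
      max(m$wavelength) > max(basis$wavelength)) {
    stop("basis does not cover the spectrum's wavelength range",
         call. = FALSE)
  }
  len_corr <- 1 - constants$k / n_residues
  cols <- setdiff(names(basis), "wavelength")
  B <- vapply(cols, function(cn) {
    stats::approx(basis$wavelength, basis[[cn]], xout = m$wavelength)$y
  }, numeric(nrow(m)))
  B[, "helix"] <- B[, "helix"] * len_corr
  coefs <- .simplex_ls(B, m$mre)
  names(coefs) <- cols
  est <- .helicity_estimate(coefs[["helix"]], "basis_nnls", .mre_at_222(m))
  est$coefficients <- coefs
  est
}

#' Read a CD spectrum CSV
#'
#' Expects columns `wavelength_nm`, `ellipticity_mdeg`; the metadata
#' (`conc_M`, `path_cm`, `n_residues`) may be given as arguments or as
#' constant columns of the file.
#'
#' @param path CSV path.
#' @param conc,pathlength,n_residues Metadata overrides.
#' @return A [cd_spectrum()].
#' @export
read_cd_spectrum <- function(path, conc = NULL, pathlength = NULL,
                             n_residues = NULL) {
  d <- utils::read.csv(path)
  need <- c("wavelength_nm", "ellipticity_mdeg")
  if (!all(need %in% names(d))) {
    stop("CD CSV needs columns wavelength_nm, ellipticity_mdeg",
         call. = FALSE)
  }
  conc <- conc %||% d$conc_M[1]
  pathlength <- pathlength %||% d$path_cm[1]
  n_residues <- n_residues %||% d$n_residues[1]
  cd_spectrum(d$wavelength_nm, d$ellipticity_mdeg, conc, pathlength,
              n_residues)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
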