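# Least-squares fitting of the anisotropy binding models.
#
# Both fits use Levenberg-Marquardt (minpack.lm) on pooled replicate
# residuals with log10(Kd) as the free parameter, multi-started one decade
# and a half either side of a data-driven initial value to avoid local
# minima on weak binders.

.fp_fit_result <- function(estimates, standard_errors, converged,
                           residual_norm, n_points, diagnostics = list()) {
  structure(list(estimates = estimates, standard_errors = standard_errors,
                 converged = converged, residual_norm = residual_norm,
                 n_points = n_points, diagnostics = diagnostics),
            class = "fp_fit")
}

#' @export
print.fp_fit <- function(x, ...) {
  cat("Anisotropy model fit (", if (x$converged) "converged"
      else "NOT converged", ", n = ", x$n_points, ")\n", sep = "")
  est <- x$estimates
  se <- x$standard_errors[names(est)]
  for (nm in names(est)) {
    cat(sprintf("  %-4s %12.6g  (SE %.4g)\n", nm, est[[nm]], se[[nm]]))
  }
  cat(sprintf("  residual norm: %.4g\n", x$residual_norm))
  if (length(x$diagnostics)) {
    for (nm in names(x$diagnostics)) {
      cat("  diagnostic ", nm, ": ", format(x$diagnostics[[nm]]), "\n",
          sep = "")
    }
  }
  invisible(x)
}

# Run nls.lm over multi-start log10(Kd) initial values; returns the best
# converged attempt (lowest deviance) or NULL.
.lm_multistart <- function(resid_fn, par0, lkd_name, offsets = c(-1.5, 0, 1.5)) {
  best <- NULL
  for (off in offsets) {
    p0 <- par0
    p0[[lkd_name]] <- p0[[lkd_name]] + off
    ans <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(ans)) next
    if (is.null(best) || ans$deviance < best$deviance) best <- ans
  }
  best
}

# Parameter standard errors from the LM fit (sigma^2 * (J'J)^-1).
.lm_se <- function(fit, n_par) {
  n <- length(fit$fvec)
  dof <- max(n - n_par, 1)
  s2 <- fit$deviance / dof
  vc <- tryCatch(s2 * solve(fit$hessian), error = function(e) NULL)
  if (is.null(vc)) return(rep(NA_real_, n_par))
  sqrt(pmax(diag(vc), 0))
}

# Heuristic initial log10(Kd): titrant concentration where the response
# crosses half of its observed range.
.init_lkd <- function(x, r) {
  mid <- (min(r) + max(r)) / 2
  xpos <- x[x > 0]
  if (!length(xpos)) return(1)
  i <- which.min(abs(r[x > 0] - mid))
  log10(xpos[i])
}

#' Fit the direct 1:1 anisotropy model to a titration curve
#'
#' Pooled least-squares fit of [anisotropy_direct()] over `(Kd, r0, r_b)`
#' against protein concentration. `Kd` is parameterized as `log10(Kd)` so the
#' estimate is constrained positive; `r0` and `rb` may be held fixed.
#'
#' @param curve A data frame with columns `x` (titrant concentration, nM) and
#'   `r` (anisotropy); an optional `replicate` column is pooled. Titration
#'   CSVs use the columns `conc_nM`, `anisotropy` and are mapped by
#'   [read_titration()].
#' @param lt Total labeled-peptide concentration (nM), held at the assay
#'   value (default 50).
#' @param fixed Optional named list fixing `r0` and/or `rb`.
#' @return An object of class `fp_fit` with `estimates` (`Kd`, `r0`, `rb`),
#'   `standard_errors`, `converged`, `residual_norm` and `n_points`.
#'   Non-convergence is reported through `converged = FALSE`, never an error.
#' @export
fit_direct <- function(curve, lt = 50, fixed = NULL) {
  x <- curve$x; r <- curve$r
  n <- length(r)
  fail <- function() .fp_fit_result(
    c(Kd = NA_real_, r0 = NA_real_, rb = NA_real_),
    c(Kd = NA_real_, r0 = NA_real_, rb = NA_real_),
    FALSE, NA_real_, n)
  if (n < 5 || diff(range(r)) == 0) return(fail())
  par0 <- list(lkd = .init_lkd(x, r))
  if (is.null(fixed$r0)) par0$r0 <- min(r)
  if (is.null(fixed$rb)) par0$rb <- max(r)
  resid_fn <- function(p) {
    r0 <- if (is.null(fixed$r0)) p$r0 else fixed$r0
    rb <- if (is.null(fixed$rb)) p$rb else fixed$rb
    r - (r0 + (rb - r0) * frac_bound_direct(10^p$lkd, lt, x))
  }
  fit <- .lm_multistart(resid_fn, par0, "lkd")
  if (is.null(fit) || !fit$info %in% 1:4 || !all(is.finite(unlist(fit$par)))) {
    return(fail())
  }
  p <- fit$par
  kd <- 10^p$lkd
  se_raw <- .lm_se(fit, length(p))
  names(se_raw) <- names(p)
  est <- c(Kd = kd,
           r0 = if (is.null(fixed$r0)) p$r0 else fixed$r0,
           rb = if (is.null(fixed$rb)) p$rb else fixed$rb)
  se <- c(Kd = unname(kd * log(10) * se_raw["lkd"]),
          r0 = unname(if (is.null(fixed$r0)) se_raw["r0"] else 0),
          rb = unname(if (is.null(fixed$rb)) se_raw["rb"] else 0))
  .fp_fit_result(est, se, TRUE, sqrt(fit$deviance), n)
}

#' Fit the competitive displacement model for an apparent Kd
#'
#' Pooled least-squares fit of [anisotropy_competition()] over
#' `(Kd2, r0, rb)` against competitor concentration, with the assay constants
#' `kd1`, `lst`, `pt` held fixed (defaults 13.0 / 50 / 250 nM).
#'
#' If `r_free` (the measured anisotropy of the free tracer) is supplied, the
#' fit carries the assay artifact diagnostic `baseline_below_free`: a fitted
#' baseline below the free-tracer anisotropy indicates an unintended
#' ligand-tracer interaction displacing the tracer signal.
#'
#' @param curve Data frame with columns `x` (competitor concentration, nM)
#'   and `r` (anisotropy).
#' @param kd1 Tracer dissociation constant (nM).
#' @param lst Total labeled-ligand concentration (nM).
#' @param pt Total protein concentration (nM); must exceed `lst`.
#' @param fixed Optional named list fixing `r0` and/or `rb`.
#' @param r_free Optional measured free-tracer anisotropy for the baseline
#'   diagnostic.
#' @return An `fp_fit` with estimate `Kd2` (plus `r0`, `rb`).
#' @export
fit_competition <- function(curve, kd1 = 13.0, lst = 50, pt = 250,
                            fixed = NULL, r_free = NULL) {
  if (pt <= lst) stop("assay validity requires pt > lst", call. = FALSE)
  x <- curve$x; r <- curve$r
  n <- length(r)
  fail <- function() .fp_fit_result(
    c(Kd2 = NA_real_, r0 = NA_real_, rb = NA_real_),
    c(Kd2 = NA_real_, r0 = NA_real_, rb = NA_real_),
    FALSE, NA_real_, n)
  if (n < 5 || diff(range(r)) == 0) return(fail())
  par0 <- list(lkd = .init_lkd(x, r))
  if (is.null(fixed$r0)) par0$r0 <- min(r)
  if (is.null(fixed$rb)) par0$rb <- max(r)
  resid_fn <- function(p) {
    r0 <- if (is.null(fixed$r0)) p$r0 else fixed$r0
    rb <- if (is.null(fixed$rb)) p$rb else fixed$rb
    r - (r0 + (rb - r0) *
           frac_bound_competition(kd1, 10^p$lkd, lst, x, pt,
                                  validate = FALSE))
  }
  fit <- .lm_multistart(resid_fn, par0, "lkd")
  if (is.null(fit) || !fit$info %in% 1:4 || !all(is.finite(unlist(fit$par)))) {
    return(fail())
  }
  p <- fit$par
  kd2 <- 10^p$lkd
  se_raw <- .lm_se(fit, length(p))
  names(se_raw) <- names(p)
  r0_hat <- if (is.null(fixed$r0)) p$r0 else fixed$r0
  est <- c(Kd2 = kd2, r0 = r0_hat,
           rb = if (is.null(fixed$rb)) p$rb else fixed$rb)
  se <- c(Kd2 = unname(kd2 * log(10) * se_raw["lkd"]),
          r0 = unname(if (is.null(fixed$r0)) se_raw["r0"] else 0),
          rb = unname(if (is.null(fixed$rb)) se_raw["rb"] else 0))
  diag <- list()
  if (!is.null(r_free)) {
    diag$baseline_below_free <- min(r0_hat, min(r)) < r_free
  }
  .fp_fit_result(est, se, TRUE, sqrt(fit$deviance), n, diag)
}

#' Read a titration CSV
#'
#' Expects columns `conc_nM`, `anisotropy` and optionally `replicate`.
#'
#' @param path Path to the CSV file.
#' @return A data frame with columns `x`, `r` (and `replicate` if present).
#' @export
read_titration <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("conc_nM", "anisotropy")
  if (!all(need %in% names(d))) {
    stop("titration CSV needs columns conc_nM, anisotropy", call. = FALSE)
  }
  out <- data.frame(x = d$conc_nM, r = d$anisotropy)
  if ("replicate" %in% names(d)) out$replicate <- d$replicate
  out
}
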