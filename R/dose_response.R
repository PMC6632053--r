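# Normalization and potency analysis of cellular dose-response readouts.
#
# Reporter signals are expressed as percent of the maximal p53 induction
# control (50 uM azide-stapled-peptide control well); LDH release as percent
# of the lytic-peptide control. EC50s come from a four-parameter logistic on
# log10(dose), with potencies above the highest tested dose reported as
# right-censored bounds (">50" by the library convention).

#' Censored potency value
#'
#' Represents a potency known only as a bound, e.g. `">50"` uM when no
#' activity was observed up to the highest tested dose.
#'
#' @param bound Numeric bound.
#' @param unit Unit label (default `"uM"`).
#' @return An object of class `censored`.
#' @export
censored <- function(bound, unit = "uM") {
  stopifnot(is.numeric(bound), length(bound) == 1, is.finite(bound))
  structure(list(bound = bound, direction = "greater", unit = unit),
            class = "censored")
}

#' Test for a censored value
#' @param x Any object.
#' @return `TRUE` for objects created by [censored()].
#' @export
is_censored <- function(x) inherits(x, "censored")

#' @export
format.censored <- function(x, ...) paste0(">", format(x$bound, ...))

#' @export
print.censored <- function(x, ...) {
  cat(format(x), x$unit, "\n")
  invisible(x)
}

.normalize_percent <- function(raw, max_control, background, what) {
  if (max_control <= background) {
    stop(sprintf("degenerate %s controls: max_control <= background", what),
         call. = FALSE)
  }
  out <- 100 * (raw - background) / (max_control - background)
  neg <- which(out < 0)
  if (length(neg)) {
    # below-background readings are reported as-is, flagged, never zeroed
    attr(out, "negative") <- neg
  }
  out
}

#' Normalize reporter signal to percent of maximal induction
#'
#' `100 * (raw - background) / (max_control - background)`. Values may exceed
#' 100; values below 0 are kept as-is with their indices attached as the
#' `"negative"` attribute.
#'
#' @param raw Raw signal series.
#' @param max_control Signal of the maximal-induction control.
#' @param background Background (vehicle) signal.
#' @return Percent-of-max series.
#' @export
normalize_reporter <- function(raw, max_control, background) {
  .normalize_percent(raw, max_control, background, "reporter")
}

#' Normalize LDH release to percent of the lytic-control release
#'
#' Same affine contract as [normalize_reporter()], with the lytic peptide
#' defining 100% membrane disruption.
#'
#' @param raw Raw signal series.
#' @param lytic_control Signal of the lytic-peptide control.
#' @param background Background signal.
#' @return Percent-of-max series.
#' @export
normalize_ldh <- function(raw, lytic_control, background) {
  .normalize_percent(raw, lytic_control, background, "LDH")
}

# 4PL on log10 dose; hill > 0 means response rises with dose.
.logistic4 <- function(dose, bottom, top, lec50, hill) {
  bottom + (top - bottom) / (1 + 10^(hill * (lec50 - log10(dose))))
}

#' Fit a four-parameter logistic and extract the EC50
#'
#' Fits `bottom + (top - bottom) / (1 + 10^(hill (log10 EC50 - log10 d)))` to
#' a normalized dose-response curve by Levenberg-Marquardt least squares.
#' The result is censored to `">max_tested"` when (i) the fit does not
#' converge, (ii) the fitted EC50 exceeds the highest tested dose, or
#' (iii) the curve fails the activity criterion
#' `top - bottom >= 20` (percent of the control range).
#'
#' @param dose Dose series (uM, increasing), `>= 5` points.
#' @param response Normalized response series (percent of max control).
#' @param max_tested Highest tested dose (uM); the censoring bound.
#' @return An object of class `potency_result` with fields `ec50` (numeric
#'   uM, or a [censored()] bound), `hill`, `top`, `bottom`, `converged`.
#'   Censored results carry `NA` for `hill`/`top`/`bottom`.
#' @examples
#' d <- 10^seq(-2, log10(50), length.out = 9)
#' y <- 100 / (1 + 10^(1.5 * (log10(0.54) - log10(d))))
#' fit_ec50(d, y)$ec50
#' @export
fit_ec50 <- function(dose, response, max_tested = 50) {
  stopifnot(length(dose) == length(response))
  if (any(dose <= 0)) stop("doses must be > 0", call. = FALSE)
  if (length(dose) < 5) stop("need at least 5 doses", call. = FALSE)
  censored_result <- function(converged) {
    structure(list(ec50 = censored(max_tested), hill = NA_real_,
                   top = NA_real_, bottom = NA_real_, converged = converged),
              class = "potency_result")
  }
  if (diff(range(response)) == 0) return(censored_result(FALSE))
  par0 <- list(bottom = 0, top = max(response),
               lec50 = log10(stats::median(dose)), hill = 1)
  resid_fn <- function(p) {
    response - .logistic4(dose, p$bottom, p$top, p$lec50, p$hill)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 200, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4 ||
      !all(is.finite(unlist(fit$par)))) {
    return(censored_result(FALSE))
  }
  p <- fit$par
  ec50 <- 10^p$lec50
  if (ec50 > max_tested || (p$top - p$bottom) < 20) {
    return(censored_result(TRUE))
  }
  structure(list(ec50 = ec50, hill = p$hill, top = p$top, bottom = p$bottom,
                 converged = TRUE),
            class = "potency_result")
}

#' @export
print.potency_result <- function(x, ...) {
  if (is_censored(x$ec50)) {
    cat("EC50:", format(x$ec50), "uM (censored)\n")
  } else {
    cat(sprintf("EC50: %.4g uM  (hill %.3g, top %.3g%%, bottom %.3g%%)\n",
                x$ec50, x$hill, x$top, x$bottom))
  }
  invisible(x)
}

# round half away from zero at integer precision (printed-table convention)
.round_half_up <- function(x) floor(x + 0.5)

#' Cell/target potency ratio
#'
#' The fold-shift between cellular activity and biochemical binding affinity:
#' `ratio = EC50 (nM) / Kd (nM) = 1000 * ec50_uM / kd_nM`, rounded half-up
#' to the nearest integer as in the printed library tables. A censored EC50
#' `">X"` propagates to a censored ratio `">round(1000 X / Kd)"`. Used as a
#' permeability proxy: smaller ratios indicate better cellular access.
#'
#' @param ec50 Cellular EC50 in uM (numeric), or a [censored()] bound.
#' @param kd Binding dissociation constant in nM, `> 0`.
#' @return Integer ratio, or a `censored` ratio (unit `""`).
#' @examples
#' cell_target_ratio(0.54, 18.6)          # 29
#' cell_target_ratio(censored(50), 6485)  # ">8"
#' @export
cell_target_ratio <- function(ec50, kd) {
  if (!is.numeric(kd) || kd <= 0) stop("kd must be > 0", call. = FALSE)
  if (is_censored(ec50)) {
    return(censored(.round_half_up(1000 * ec50$bound / kd), unit = ""))
  }
  if (!is.numeric(ec50) || ec50 < 0) stop("invalid ec50", call. = FALSE)
  as.integer(.round_half_up(1000 * ec50 / kd))
}
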