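# Table-level analytics over a peptide SAR library: scan fold-changes,
# series summaries, aggregation conventions, stability normalization and the
# lipophilicity ~ cell/target-ratio correlation.
#
# Missing helicity ("ND") and right-censored potencies (">50") are
# first-class states carried through every operation, never coerced.

# parse a possibly-censored numeric string: "37", ">50", "ND", "" -> list
.parse_num <- function(x) {
  x <- trimws(as.character(x))
  cens <- grepl("^>", x)
  x2 <- sub("^>", "", x)
  val <- suppressWarnings(as.numeric(x2))
  val[x %in% c("ND", "", "NA")] <- NA
  cens[is.na(val)] <- FALSE
  list(value = val, censored = cens)
}

#' Read a peptide library CSV
#'
#' Expected columns: `name`, `notation`, `series`, `helicity_pct` (numeric or
#' `"ND"`), `ec50_uM` (numeric or `">50"`), `kd_nM`; optional `label`,
#' `ratio_printed`, `logd`, `alogp`, `parent_name`. `"ND"` and the `">"`
#' prefix are the only sentinel dialects.
#'
#' @param path CSV path.
#' @return A data frame of class `library_table` with `helicity_pct`,
#'   `ec50_uM`, `kd_nM` numeric, plus the logical `ec50_censored`.
#' @export
read_library <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("name", "notation", "series", "helicity_pct", "ec50_uM", "kd_nM")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("library CSV missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  as_library_table(d)
}

#' Coerce a raw data frame to a library table
#'
#' Parses the `"ND"` / `">"` sentinels of `helicity_pct` and `ec50_uM` and
#' validates parent references and positive Kd values.
#'
#' @param d A data frame with the library CSV columns.
#' @return A `library_table` data frame.
#' @export
as_library_table <- function(d) {
  hel <- .parse_num(d$helicity_pct)
  ec <- .parse_num(d$ec50_uM)
  d$helicity_pct <- hel$value
  d$ec50_uM <- ec$value
  d$ec50_censored <- ec$censored
  d$kd_nM <- suppressWarnings(as.numeric(d$kd_nM))
  if (any(!is.na(d$kd_nM) & d$kd_nM <= 0)) {
    stop("kd_nM must be > 0 where present", call. = FALSE)
  }
  if (!is.null(d$parent_name)) {
    refs <- setdiff(d$parent_name[nzchar(d$parent_name) &
                                    !is.na(d$parent_name)], d$name)
    if (length(refs)) {
      stop("unknown parent_name: ", paste(unique(refs), collapse = ", "),
           call. = FALSE)
    }
  }
  class(d) <- c("library_table", "data.frame")
  d
}

.row_by_name <- function(table, name) {
  i <- which(table$name == name)
  if (!length(i)) stop(sprintf("no row named '%s'", name), call. = FALSE)
  table[i[1], ]
}

#' Kd fold-change of a variant relative to its parent
#'
#' `kd(variant) / kd(parent)`; values >> 1 mark substitutions that degrade
#' target binding (interfacial Ala/D substitutions run roughly 10- to
#' 100-fold).
#'
#' @param table A `library_table`.
#' @param name Variant row name.
#' @param parent_name Parent row name; defaults to the row's `parent_name`
#'   column.
#' @return Numeric fold-change, or `NA` when either Kd is missing.
#' @export
fold_change_vs_parent <- function(table, name, parent_name = NULL) {
  row <- .row_by_name(table, name)
  parent_name <- parent_name %||%
    if (!is.null(row$parent_name) && nzchar(row$parent_name)) {
      row$parent_name
    } else NULL
  if (is.null(parent_name)) return(NA_real_)
  parent <- .row_by_name(table, parent_name)
  if (is.na(row$kd_nM) || is.na(parent$kd_nM)) return(NA_real_)
  row$kd_nM / parent$kd_nM
}

#' Helicity summary of a library series
#'
#' Arithmetic mean, min and max of the non-missing helicity values in a
#' series ("ND" entries are excluded and counted).
#'
#' @param table A `library_table`.
#' @param series Series tag to summarize.
#' @return List with `mean`, `min`, `max`, `n`, `n_missing`.
#' @export
series_helicity_summary <- function(table, series) {
  h <- table$helicity_pct[table$series == series]
  if (!length(h)) stop(sprintf("no rows in series '%s'", series),
                       call. = FALSE)
  hv <- h[!is.na(h)]
  if (!length(hv)) stop("no measurable helicity in series", call. = FALSE)
  list(mean = mean(hv), min = min(hv), max = max(hv), n = length(hv),
       n_missing = sum(is.na(h)))
}

#' Aggregate replicate potency or helicity values
#'
#' Binding and cellular potencies aggregate as geometric means; helicity as
#' the arithmetic mean (the reporting conventions of the source assays).
#'
#' @param values Numeric replicate values; must be positive for geometric
#'   kinds.
#' @param kind One of `"binding"`, `"cellular"`, `"helicity"`.
#' @return Scalar summary value.
#' @examples
#' aggregate_potency(c(10, 1000), "binding")  # 100
#' @export
aggregate_potency <- function(values, kind = c("binding", "cellular",
                                               "helicity")) {
  kind <- match.arg(kind)
  if (kind == "helicity") return(mean(values))
  if (any(values <= 0)) {
    stop("geometric aggregation requires positive values", call. = FALSE)
  }
  exp(mean(log(values)))
}

#' Normalize a stability timecourse to its t = 0 amount
#'
#' @param time_h Time points in hours; must include 0.
#' @param amount Measured amounts (same length); `amount[time_h == 0]` must
#'   be positive.
#' @return A data frame of class `stability_timecourse` with `time_h` and
#'   `remaining_pct` (100 at t = 0).
#' @export
normalize_stability <- function(time_h, amount) {
  stopifnot(length(time_h) == length(amount))
  i0 <- which(time_h == 0)
  if (!length(i0)) stop("t = 0 measurement required", call. = FALSE)
  a0 <- amount[i0[1]]
  if (is.na(a0) || a0 <= 0) stop("t = 0 amount must be > 0", call. = FALSE)
  structure(data.frame(time_h = time_h, remaining_pct = 100 * amount / a0),
            class = c("stability_timecourse", "data.frame"))
}

#' Regress cell/target ratios on lipophilicity
#'
#' Ordinary least squares of the (by default log10-transformed) cell/target
#' ratio on a lipophilicity measure. Ratios are recomputed unrounded from
#' `ec50_uM` and `kd_nM`; censored rows are excluded and counted. Ratios in
#' the library span roughly 2-777, so the log10 transform keeps the linear
#' fit from being dominated by weakly permeable outliers; raw-ratio mode is
#' retained as an option.
#'
#' @param table A `library_table` with a `logd` and/or `alogp` column.
#' @param x Predictor: `"logd"` (HPLC-LogD) or `"alogp"`.
#' @param y_transform `"log10_ratio"` (default) or `"ratio"`.
#' @return List of class `lipo_regression`: `slope`, `intercept`,
#'   `r_squared`, `n_points`, `n_censored_excluded`, `x_name`, `y_name`,
#'   `degenerate`.
#' @export
correlate_lipophilicity <- function(table, x = c("logd", "alogp"),
                                    y_transform = c("log10_ratio", "ratio")) {
  x <- match.arg(x)
  y_transform <- match.arg(y_transform)
  if (is.null(table[[x]])) {
    stop(sprintf("library table has no '%s' column", x), call. = FALSE)
  }
  usable <- !table$ec50_censored & !is.na(table$ec50_uM) &
    !is.na(table$kd_nM) & !is.na(table[[x]])
  n_cens <- sum(table$ec50_censored & !is.na(table[[x]]))
  if (sum(usable) < 3) stop("fewer than 3 usable rows", call. = FALSE)
  ratio <- 1000 * table$ec50_uM[usable] / table$kd_nM[usable]
  yy <- if (y_transform == "log10_ratio") log10(ratio) else ratio
  xx <- table[[x]][usable]
  degenerate <- stats::var(yy) == 0 || stats::var(xx) == 0
  fit <- stats::lm(yy ~ xx)
  r2 <- if (degenerate) 0 else stats::cor(xx, yy)^2
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, n_points = sum(usable),
                 n_censored_excluded = n_cens, x_name = x,
                 y_name = y_transform, degenerate = degenerate),
            class = "lipo_regression")
}

#' @export
print.lipo_regression <- function(x, ...) {
  cat(sprintf("%s ~ %s: slope %.3g, intercept %.3g, R^2 = %.3f (n = %d",
              x$y_name, x$x_name, x$slope, x$intercept, x$r_squared,
              x$n_points))
  if (x$n_censored_excluded) {
    cat(",", x$n_censored_excluded, "censored excluded")
  }
  cat(")\n")
  if (x$degenerate) cat("  [degenerate: zero variance]\n")
  invisible(x)
}

# render a computed ratio the way the printed tables do
.render_ratio <- function(ec50, censored, kd) {
  if (is.na(ec50) || is.na(kd)) return(NA_character_)
  r <- cell_target_ratio(if (censored) censored(ec50) else ec50, kd)
  if (is_censored(r)) format(r) else as.character(r)
}

#' Recompute cell/target ratios and lint them against printed values
#'
#' Recomputes every row's ratio from its `ec50_uM` / `kd_nM` and compares it
#' with the `ratio_printed` column where available. Disagreements (typically
#' +/- 1-2, presumed to stem from unrounded source potencies) are flagged,
#' never forced to match. Scan labels are also linted against the parsed
#' notation via [lint_scan_label()].
#'
#' @param table A `library_table`.
#' @return Data frame with `name`, `ratio_printed`, `ratio_computed`,
#'   `ratio_match`, `label_ok`.
#' @export
ratio_lint <- function(table) {
  out <- data.frame(name = table$name,
                    ratio_printed = if (!is.null(table$ratio_printed)) {
                      as.character(table$ratio_printed)
                    } else NA_character_,
                    ratio_computed = NA_character_,
                    ratio_match = NA, label_ok = NA,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(table))) {
    out$ratio_computed[i] <- .render_ratio(table$ec50_uM[i],
                                           table$ec50_censored[i],
                                           table$kd_nM[i])
    if (!is.na(out$ratio_printed[i]) && nzchar(out$ratio_printed[i]) &&
        !is.na(out$ratio_computed[i])) {
      out$ratio_match[i] <- out$ratio_printed[i] == out$ratio_computed[i]
    }
    lbl <- if (!is.null(table$label) && nzchar(table$label[i] %||% "") &&
               !is.na(table$label[i])) {
      table$label[i]
    } else table$name[i]
    lint <- tryCatch({
      pep <- parse_peptide(table$notation[i], name = table$name[i])
      lint_scan_label(lbl, pep)
    }, error = function(e) NULL)
    if (!is.null(lint) && nrow(lint)) out$label_ok[i] <- all(lint$ok)
  }
  out
}

#' Full library report
#'
#' Per-series helicity summaries, the ratio/label lint table, and (when a
#' lipophilicity column is present) the ratio correlation.
#'
#' @param table A `library_table`.
#' @return List with `series_helicity`, `lint`, and optionally `regression`.
#' @export
library_report <- function(table) {
  series <- unique(table$series)
  hel <- lapply(series, function(s) {
    tryCatch(series_helicity_summary(table, s), error = function(e) NULL)
  })
  names(hel) <- series
  out <- list(series_helicity = hel[!vapply(hel, is.null, TRUE)],
              lint = ratio_lint(table))
  if (!is.null(table$logd) && sum(!is.na(table$logd)) >= 3) {
    out$regression <- tryCatch(correlate_lipophilicity(table, "logd"),
                               error = function(e) NULL)
  }
  out
}
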