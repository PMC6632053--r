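# Packaged transcription of the published MP-292 / MP-081 SAR tables.

#' The packaged Mdm2 stapled-peptide library table
#'
#' Transcription of the published SAR tables: the MP-292 alanine scan
#' (series `"A"`), the MP-292 D-amino-acid scan (series `"B"`), the linear
#' MP-189 D-scan (series `"C"`), and the MP-081 helix-inducer/breaker series
#' (series `"table2"`). Each row carries the sequence notation, helicity %
#' (`NA` where printed as "ND"), cellular EC50 in uM (right-censored rows
#' such as ">50" carry the bound with `ec50_censored = TRUE`), Mdm2 Kd in nM,
#' and the printed cell/target ratio (verbatim, including ">" bounds).
#'
#' Printed helicity and potency values are input data here (golden fixtures
#' for table analytics), not reproduction targets of the estimators.
#'
#' @return A `library_table` data frame with 50 rows.
#' @examples
#' lib <- mdm2_peptide_library()
#' subset(lib, name == "MP-292")$kd_nM
#' @export
mdm2_peptide_library <- function() {
  path <- system.file("extdata", "mdm2_peptide_library.csv",
                      package = "helixscan")
  if (!nzchar(path)) stop("packaged library fixture not found", call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  as_library_table(d)
}
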