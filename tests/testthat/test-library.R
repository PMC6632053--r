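test_that("alanine-scan series helicity summary matches the printed range", {
  lib <- mdm2_peptide_library()
  s <- series_helicity_summary(lib, "A")
  expect_equal(s$min, 27.6)
  expect_equal(s$max, 53.3)
  expect_equal(s$mean, 40.8, tolerance = 1e-3)
  expect_equal(s$n, 9)
  expect_equal(s$n_missing, 2)  # the two "ND" rows
  expect_error(series_helicity_summary(lib, "nope"), "no rows")
})

test_that("single-row series collapse mean, min and max", {
  t1 <- as_library_table(data.frame(
    name = "X", notation = "Ac-LTF[R8]EYWQL[Cba][S5]SAA-amide",
    series = "s", helicity_pct = "41.2", ec50_uM = "1", kd_nM = 10,
    parent_name = ""))
  s <- series_helicity_summary(t1, "s")
  expect_equal(c(s$mean, s$min, s$max), rep(41.2, 3))
})

test_that("Kd fold-changes vs parent reproduce the scan arithmetic", {
  lib <- mdm2_peptide_library()
  expect_equal(fold_change_vs_parent(lib, "F3A"), 3600 / 18.6,
               tolerance = 1e-12)
  expect_equal(fold_change_vs_parent(lib, "Cba10A"), 176 / 18.6,
               tolerance = 1e-12)
  expect_equal(fold_change_vs_parent(lib, "MP-292", "MP-292"), 1)
  # interfacial Ala hits degrade binding 10-100x (and beyond)
  for (nm in c("F3A", "W7A", "Cba10A")) {
    expect_gte(fold_change_vs_parent(lib, nm), 9)
  }
  # missing Kd propagates as NA, not an error
  lib2 <- lib
  lib2$kd_nM[lib2$name == "F3A"] <- NA
  expect_true(is.na(fold_change_vs_parent(lib2, "F3A")))
  # rows without a parent yield NA
  expect_true(is.na(fold_change_vs_parent(lib, "MP-292")))
})

test_that("aggregation conventions: geometric for potency, arithmetic for helicity", {
  expect_equal(aggregate_potency(c(10, 1000), "binding"), 100)
  expect_equal(aggregate_potency(c(30, 30, 30), "cellular"), 30)
  expect_equal(aggregate_potency(c(20, 40, 60), "helicity"), 40)
  expect_error(aggregate_potency(c(1, 0), "binding"), "positive")
})

test_that("stability timecourses normalize to the t = 0 amount", {
  tc <- normalize_stability(c(0, 1, 2, 4, 22), c(8, 8, 8, 8, 8))
  expect_equal(tc$remaining_pct, rep(100, 5))
  tc2 <- normalize_stability(c(0, 22), c(10, 5))
  expect_equal(tc2$remaining_pct[2], 50)
  expect_error(normalize_stability(c(1, 2), c(1, 1)), "t = 0")
  expect_error(normalize_stability(c(0, 1), c(0, 1)), "> 0")
})

test_that("lipophilicity regression recovers exact and degenerate cases", {
  mk <- function(logd, ratio) {
    as_library_table(data.frame(
      name = paste0("P", seq_along(logd)),
      notation = "Ac-LTF[R8]EYWQL[Cba][S5]SAA-amide", series = "s",
      helicity_pct = "40", ec50_uM = format(ratio * 20 / 1000, digits = 12),
      kd_nM = 20, logd = logd, parent_name = ""))
  }
  logd <- c(1, 2, 3, 4, 5)
  # exact line in log10-ratio space: y = 2x + 1
  tab <- mk(logd, 10^(2 * logd + 1))
  r <- correlate_lipophilicity(tab, "logd")
  expect_equal(r$r_squared, 1, tolerance = 1e-9)
  expect_equal(r$slope, 2, tolerance = 1e-6)
  expect_equal(r$intercept, 1, tolerance = 1e-6)
  # constant y is degenerate with r_squared 0 by convention
  flat <- correlate_lipophilicity(mk(logd, rep(100, 5)), "logd")
  expect_equal(flat$r_squared, 0)
  expect_true(flat$degenerate)
  # row order invariance
  perm <- tab[c(3, 1, 5, 2, 4), ]
  expect_equal(correlate_lipophilicity(perm, "logd")$r_squared,
               r$r_squared)
  expect_error(correlate_lipophilicity(tab[1:2, ], "logd"), "3 usable")
  expect_error(correlate_lipophilicity(tab, "alogp"), "alogp")
})

test_that("censored rows are excluded from the regression and counted", {
  d <- data.frame(
    name = paste0("P", 1:6),
    notation = "Ac-LTF[R8]EYWQL[Cba][S5]SAA-amide", series = "s",
    helicity_pct = "40",
    ec50_uM = c("1", "2", "4", "8", ">50", ">50"),
    kd_nM = 20, logd = 1:6, parent_name = "")
  tab <- as_library_table(d)
  r <- correlate_lipophilicity(tab, "logd")
  expect_equal(r$n_points, 4)
  expect_equal(r$n_censored_excluded, 2)
})

test_that("ratio lint matches the audited rows and flags the discrepant ones", {
  lib <- mdm2_peptide_library()
  lint <- ratio_lint(lib)
  audited <- c("MP-292", "F3A", "S12(D-Ser)", "MP-189", "MP-384",
               "Q8(D-Gln)", "L1G,E5G,A8G", "F3(D-Phe)")
  expect_true(all(lint$ratio_match[lint$name %in% audited]))
  # known printed-vs-recomputed disagreements are flagged, not forced
  flagged <- lint$name[!is.na(lint$ratio_match) & !lint$ratio_match]
  expect_true(all(c("Cba10A", "E5(D-Glu)") %in% flagged))
  expect_equal(lint$ratio_computed[lint$name == "Cba10A"], "63")
  # the D-Trp scan label mismatch surfaces through the label lint
  expect_false(lint$label_ok[lint$name == "MP-384"])
  expect_true(lint$label_ok[lint$name == "F3A"])
})

test_that("library CSVs round-trip through read_library with sentinels intact", {
  lib <- mdm2_peptide_library()
  path <- withr::local_tempfile(fileext = ".csv")
  raw <- utils::read.csv(system.file("extdata", "mdm2_peptide_library.csv",
                                     package = "helixscan"),
                         stringsAsFactors = FALSE, encoding = "UTF-8")
  write.csv(raw, path, row.names = FALSE, fileEncoding = "UTF-8")
  back <- read_library(path)
  expect_equal(back$ec50_uM, lib$ec50_uM)
  expect_equal(back$ec50_censored, lib$ec50_censored)
  expect_equal(sum(back$ec50_censored), 7)  # the seven ">50" rows
  expect_equal(sum(is.na(back$helicity_pct)), 3)  # the three "ND" rows
  expect_error(read_library(textConnection("name,foo\nx,1")), "missing")
  # dangling parent references are rejected
  bad <- raw[1:2, ]
  bad$parent_name <- c("", "GHOST")
  expect_error(as_library_table(bad), "GHOST")
})

test_that("library report bundles summaries, lint and regression", {
  lib <- gen_library(n_peptides = 20, seed = 5)
  rep <- library_report(lib)
  expect_true("synthetic" %in% names(rep$series_helicity))
  expect_equal(nrow(rep$lint), 20)
  expect_s3_class(rep$regression, "lipo_regression")
})
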