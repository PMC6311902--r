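test_that("read_mrm_table parses the Area-Ratio layout and reports counts", {
  path <- withr::local_tempfile(fileext = ".csv")
  rec <- toy_ratio_records(n_subj = 2, peptides = c("p1", "p2"),
                           values = c(1.5, 2.5, 0.5, 4))
  utils::write.csv(rec[, c("sample_id", "group", "run", "protein", "peptide",
                           "value")] |>
                     stats::setNames(c("Sample ID", "Group", "Run", "Protein",
                                       "Peptide", "Area Ratio")),
                   path, row.names = FALSE)
  tab <- suppressMessages(read_mrm_table(
    path, dialect = c(sample_id = "Sample ID", group = "Group", run = "Run",
                      protein = "Protein", peptide = "Peptide",
                      area_ratio = "Area Ratio")))
  expect_s3_class(tab, "mrm_table")
  expect_identical(nrow(tab$records), 4L)
  expect_identical(length(unique(tab$records$sample_id)), 2L)
  expect_identical(length(unique(tab$records$protein)), 1L)
  expect_identical(length(unique(tab$records$peptide)), 2L)
  expect_identical(tab$scale, "linear")
})

test_that("read_mrm_table handles empty, malformed and pair-layout input", {
  # header-only file: empty table with a warning
  p1 <- withr::local_tempfile(fileext = ".csv")
  writeLines("sample_id,group,run,protein,peptide,area_ratio", p1)
  expect_warning(tab <- suppressMessages(read_mrm_table(p1)), "no usable")
  expect_identical(nrow(tab$records), 0L)

  # missing required column is named in the error
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,group,run,protein,area_ratio", "S1,1,R1,P1,2"), p2)
  expect_error(suppressMessages(read_mrm_table(p2)), "peptide")

  # duplicated key is a data error naming the key
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,group,run,protein,peptide,area_ratio",
               "S1,1,R1,P1,p1,2", "S1,1,R1,P1,p1,3"), p3)
  expect_error(suppressMessages(read_mrm_table(p3)), "S1/R1/P1/p1")

  # non-positive values: rejected by default, dropped on request
  p4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,group,run,protein,peptide,area_ratio",
               "S1,1,R1,P1,p1,2", "S2,2,R2,P1,p1,0"), p4)
  expect_error(suppressMessages(read_mrm_table(p4)), "non-positive")
  tab4 <- suppressMessages(read_mrm_table(p4, nonpositive = "drop"))
  expect_identical(nrow(tab4$records), 1L)

  # raw-pair layout becomes two channel records per row
  p5 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste("sample_id", "group", "run", "protein", "peptide",
                     "intensity_endogenous", "intensity_reference",
                     sep = "\t"),
               paste("S1", "1", "R1", "P1", "p1", "6", "3", sep = "\t")), p5)
  tab5 <- suppressMessages(read_mrm_table(p5))
  expect_identical(sort(tab5$records$channel), c("endogenous", "reference"))

  # transition-level duplicates roll up to the mean of log2 values
  p6 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,group,run,protein,peptide,area_ratio",
               "S1,1,R1,P1,p1,2", "S1,1,R1,P1,p1,8"), p6)
  tab6 <- suppressMessages(read_mrm_table(p6, rollup = "mean"))
  expect_equal(tab6$records$value, 4)   # 2^mean(log2(2), log2(8))
})

test_that("log2_relative_intensity forms ratios and cancels run effects", {
  # powers of two: ratio 0.25 -> -2, endo 2 / ref 1 -> 1, equal -> 0
  tab <- toy_ratio_table(n_subj = 2, peptides = "p1", values = c(0.25, 8))
  out <- log2_relative_intensity(tab)
  expect_identical(out$scale, "log2_ratio")
  expect_equal(out$records$value, c(-2, 3))

  pair <- mrm_table(rbind(
    data.frame(sample_id = "S1", group = "1", run = "R1", protein = "P1",
               peptide = "p1", value = 2, channel = "endogenous"),
    data.frame(sample_id = "S1", group = "1", run = "R1", protein = "P1",
               peptide = "p2", value = 5, channel = "endogenous"),
    data.frame(sample_id = "S1", group = "1", run = "R1", protein = "P1",
               peptide = "p1", value = 1, channel = "reference"),
    data.frame(sample_id = "S1", group = "1", run = "R1", protein = "P1",
               peptide = "p2", value = 5, channel = "reference")))
  out2 <- log2_relative_intensity(pair)
  expect_equal(sort(out2$records$value), c(0, 1))

  # an endogenous record without its reference is an error naming the key
  orphan <- mrm_table(data.frame(
    sample_id = "S1", group = "1", run = "R9", protein = "P1",
    peptide = "p1", value = 2, channel = "endogenous"))
  expect_error(log2_relative_intensity(orphan), "R9/P1/p1")

  # round-trip: exponentiating recovers the Area Ratios to 1e-12 relative
  vals <- c(0.3, 1.7, 2.22, 100.5)
  rt <- log2_relative_intensity(toy_ratio_table(n_subj = 2, peptides = "p1",
                                                values = vals[1:2]))
  expect_equal(2^rt$records$value, vals[1:2], tolerance = 1e-12)
})

test_that("quantile_normalize matches the rank-mean oracle and is idempotent", {
  mk <- function(v1, v2) {
    mrm_table(data.frame(
      sample_id = rep(c("S1", "S2"), each = length(v1)),
      group = rep(c("1", "2"), each = length(v1)),
      run = rep(c("R1", "R2"), each = length(v1)),
      protein = "P1", peptide = rep(paste0("p", seq_along(v1)), 2),
      value = c(v1, v2), channel = "ratio"), scale = "log2_ratio",
      validate = FALSE)
  }
  # hand rank-mean oracle: (1,2,3) and (4,5,6) both become (2.5, 3.5, 4.5)
  out <- quantile_normalize(mk(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(out$records$value, rep(c(2.5, 3.5, 4.5), 2))

  # ties share the averaged target quantile: (1,1,3) vs (2,4,6)
  out2 <- quantile_normalize(mk(c(1, 1, 3), c(2, 4, 6)))
  expect_equal(out2$records$value[1:3], c(2, 2, 4.5))
  expect_equal(out2$records$value[4:6], c(1.5, 2.5, 4.5))

  # identical samples are unchanged; the map is idempotent
  same <- mk(c(0.2, -1, 4), c(0.2, -1, 4))
  expect_equal(quantile_normalize(same)$records$value, same$records$value)
  once <- quantile_normalize(mk(c(5, 0, 2), c(1, 3, 9)))
  twice <- quantile_normalize(once)
  expect_equal(twice$records$value, once$records$value, tolerance = 1e-12)

  # single sample: warning, no-op
  single <- mrm_table(data.frame(sample_id = "S1", group = "1", run = "R1",
                                 protein = "P1", peptide = c("p1", "p2"),
                                 value = c(1, 2), channel = "ratio"),
                      scale = "log2_ratio", validate = FALSE)
  expect_warning(out3 <- quantile_normalize(single), "fewer than two")
  expect_equal(out3$records$value, c(1, 2))
})

test_that("build_protein_matrix assembles complete cases deterministically", {
  tab <- log2_relative_intensity(toy_ratio_table(n_subj = 4))
  pm <- build_protein_matrix(tab, "P1", ref_group = "1")
  expect_identical(dim(pm$y), c(4L, 2L))
  expect_identical(pm$z, c(0L, 1L, 0L, 1L))  # groups alternate 1,2,1,2
  expect_identical(pm$sample_ids, sprintf("S%02d", 1:4))

  # permutation of record order leaves the matrix unchanged
  shuf <- tab
  set.seed(1)
  shuf$records <- shuf$records[sample(nrow(shuf$records)), ]
  pm2 <- build_protein_matrix(shuf, "P1", ref_group = "1")
  expect_identical(pm2$y, pm$y)

  # a subject missing one peptide is dropped with a message
  drop1 <- tab
  drop1$records <- drop1$records[-1L, ]
  expect_message(pm3 <- build_protein_matrix(drop1, "P1", ref_group = "1"),
                 "dropped 1")
  expect_identical(nrow(pm3$y), 3L)

  # single-peptide proteins are legitimate (K = 1)
  k1 <- log2_relative_intensity(toy_ratio_table(n_subj = 4, peptides = "p1"))
  pm4 <- build_protein_matrix(k1, "P1", ref_group = "1")
  expect_identical(dim(pm4$y), c(4L, 1L))

  expect_error(build_protein_matrix(tab, "NOPE"), "not present")
  one_group <- tab
  one_group$records$group <- "1"
  expect_error(build_protein_matrix(one_group, "P1"), "one group")
})

test_that("tables round-trip through the writer losslessly", {
  tab <- toy_ratio_table(n_subj = 2, peptides = c("p1", "p2"),
                         values = c(pi, exp(1), sqrt(2), 1 / 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_mrm_table(tab, path)
  back <- suppressMessages(read_mrm_table(path))
  expect_identical(back$records$value, tab$records$value)
  expect_identical(back$records$sample_id, tab$records$sample_id)
})
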