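test_that("a fixed seed reproduces the table bit-identically", {
  cfg <- sim_config(n_subjects = 150, seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  attr(a, "truth") <- attr(b, "truth") <- NULL
  expect_identical(a, b)
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(n_subjects = 0), "positive count")
  expect_error(sim_config(effect_r = 1), "\\[0, 1\\)")
  expect_error(sim_config(frac_retest = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(missing_rate = -0.1), "\\[0, 1\\]")
  expect_error(sim_config(latency_days_range = c(10, -10)), "interval")
})

test_that("an unrealizable planted correlation is rejected", {
  expect_error(
    simulate_cohort(sim_config(n_subjects = 300, effect_r = 0.99)),
    "cannot be realized"
  )
})

test_that("summary scores increase monotonically across latent quartiles", {
  tbl <- shared_cohort()
  truth <- attr(tbl, "truth")
  sc <- shared_scores()
  t1 <- sc[sc$timepoint == 1L, ]
  qz <- cut(truth$z, quantile(truth$z, 0:4 / 4), include.lowest = TRUE,
            labels = FALSE)
  means <- tapply(t1$rds4, qz, mean)
  expect_true(all(diff(means) > 0))
})

test_that("missingness is confined to structural/task IDPs at
           timepoint-independent positions", {
  tbl <- shared_cohort()
  map <- column_map(tbl)
  imap <- map[map$role == "idp", ]
  resting_cols <- imap$column[modality_group(imap$modality) == "resting"]
  other_cols <- setdiff(imap$column, resting_cols)
  expect_false(anyNA(tbl[resting_cols]))
  expect_gt(sum(is.na(tbl[other_cols])), 0)
  # same holes at both timepoints for retest subjects
  retest_ids <- unique(tbl$subject_id[tbl$timepoint == 2L])
  t1 <- tbl[tbl$timepoint == 1L & tbl$subject_id %in% retest_ids, ]
  t2 <- tbl[tbl$timepoint == 2L, ]
  t2 <- t2[match(t1$subject_id, t2$subject_id), ]
  expect_identical(is.na(as.matrix(t1[other_cols])),
                   is.na(as.matrix(t2[other_cols])))
})

test_that("planted per-modality reliability orders volume above task", {
  cfg <- sim_config(n_subjects = 900, seed = 21, frac_retest = 0.5,
                    missing_rate = 0,
                    reliability_per_modality = c(
                      amplitude = 0.45, full_edge = 0.45, partial_edge = 0.45,
                      task = 0.3, volume = 0.9, area = 0.85, thickness = 0.85,
                      fa = 0.85, md = 0.85, t2star = 0.85, wmh = 0.85
                    ))
  tbl <- simulate_cohort(cfg)
  map <- column_map(tbl)
  imap <- map[map$role == "idp", ]
  ids <- unique(tbl$subject_id[tbl$timepoint == 2L])
  t1 <- tbl[tbl$timepoint == 1L & tbl$subject_id %in% ids, ]
  t2 <- tbl[tbl$timepoint == 2L, ]
  t2 <- t2[match(t1$subject_id, t2$subject_id), ]
  icc_of <- function(mod) {
    cols <- imap$column[imap$modality == mod]
    median(vapply(cols, function(cc) icc_a1(t1[[cc]], t2[[cc]]), numeric(1)))
  }
  expect_gt(icc_of("volume"), icc_of("task"))
  expect_gt(icc_of("volume"), 0.75)
  expect_lt(icc_of("task"), 0.55)
})

test_that("survey retest: full trait share gives ICC 1, none gives ~0", {
  full <- simulate_survey_retest(n = 60, seed = 2, stable_share = 1,
                                 n_attention_fail = 0, n_too_fast = 0)
  rds_cols <- names(phenolink:::rds4_fields)
  s1 <- score_rds4(full[full$timepoint == 1L, rds_cols])
  s2 <- score_rds4(full[full$timepoint == 2L, rds_cols])
  expect_identical(s1, s2)
  expect_equal(icc_a1(s1, s2), 1, tolerance = 1e-12)

  none <- simulate_survey_retest(n = 400, seed = 3, stable_share = 0,
                                 n_attention_fail = 0, n_too_fast = 0)
  n1 <- score_rds4(none[none$timepoint == 1L, rds_cols])
  n2 <- score_rds4(none[none$timepoint == 2L, rds_cols])
  expect_lt(abs(icc_a1(n1, n2)), 0.12)
})

test_that("survey retest ICC at an intermediate trait share matches the
           generator's variance decomposition", {
  # oracle: population score correlation across timepoints from a large
  # Monte-Carlo draw of the same construction
  big <- simulate_survey_retest(n = 20000, seed = 10, stable_share = 0.88,
                                n_attention_fail = 0, n_too_fast = 0)
  rds_cols <- names(phenolink:::rds4_fields)
  b1 <- score_rds4(big[big$timepoint == 1L, rds_cols])
  b2 <- score_rds4(big[big$timepoint == 2L, rds_cols])
  pop_icc <- icc_a1(b1, b2)
  small <- simulate_survey_retest(n = 800, seed = 77, stable_share = 0.88,
                                  n_attention_fail = 0, n_too_fast = 0)
  s1 <- score_rds4(small[small$timepoint == 1L, rds_cols])
  s2 <- score_rds4(small[small$timepoint == 2L, rds_cols])
  expect_equal(icc_a1(s1, s2), pop_icc, tolerance = 0.08)
})

test_that("phenotype tables round-trip through CSV with their sidecar map", {
  tbl <- simulate_cohort(sim_config(n_subjects = 40, seed = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_phenotypes(tbl, path)
  back <- read_phenotypes(path)
  strip <- function(d) {
    d <- as.data.frame(d)
    attributes(d)[setdiff(names(attributes(d)),
                          c("names", "row.names", "class"))] <- NULL
    class(d) <- "data.frame"
    d
  }
  expect_equal(strip(back[names(tbl)]), strip(tbl), tolerance = 1e-12)
  expect_identical(column_map(back)$column, column_map(tbl)$column)
  expect_identical(attr(back, "provenance")$seed, 4L)
})
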