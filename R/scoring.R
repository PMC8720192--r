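#' Score the four-item Recent Depressive Symptoms scale (RDS-4)
#'
#' RDS-4 sums four scan-day items on depressed mood, disinterest,
#' restlessness and tiredness over the past two weeks (UKB fields 2050,
#' 2060, 2070, 2080). Each item is coded 1 ("not at all") to 4 ("nearly
#' every day"), so the summed score ranges 4-16. A missing or out-of-range
#' item makes the score missing; items are never imputed.
#'
#' @param items A data frame or matrix with four columns of item responses
#'   coded 1-4, one row per subject.
#' @return Integer vector of scores in 4-16, `NA` where undefined.
#' @export
#' @examples
#' score_rds4(data.frame(a = 1, b = 1, c = 1, d = 1)) # 4
score_rds4 <- function(items) {
  items <- as_numeric_matrix(items, "items")
  assert_that("RDS-4 takes exactly four items" = ncol(items) == 4L)
  items[!(items %in% 1:4)] <- NA_real_
  out <- rowSums(items)
  as.integer(out)
}

scale_specs <- list(
  phq9 = list(n_items = 9L, range = 0:3, max = 27L),
  gad7 = list(n_items = 7L, range = 0:3, max = 21L),
  n12  = list(n_items = 12L, range = 0:1, max = 12L)
)

#' Score a sum-scale questionnaire (PHQ-9, GAD-7 or N-12)
#'
#' PHQ-9 and GAD-7 items are coded 0-3 (sums 0-27 and 0-21); the twelve
#' Eysenck neuroticism items are coded 0/1 (sum 0-12). Any missing or
#' out-of-range item propagates to a missing score.
#'
#' @param items Data frame or matrix of item responses, one row per subject.
#' @param scale One of `"phq9"`, `"gad7"`, `"n12"`.
#' @return Integer vector of summed scores, `NA` where undefined.
#' @export
score_sum_scale <- function(items, scale = c("phq9", "gad7", "n12")) {
  scale <- match.arg(scale)
  spec <- scale_specs[[scale]]
  items <- as_numeric_matrix(items, "items")
  assert_that(
    "item count does not match scale" = ncol(items) == spec$n_items
  )
  items[!(items %in% spec$range)] <- NA_real_
  as.integer(rowSums(items))
}

#' Probable depression status from touchscreen fields
#'
#' Status is 1 iff the subject ever felt depressed or ever felt
#' uninterested (fields 4598 / 4631), reported a longest episode of at
#' least one week (fields 4609 / 5375), and saw a GP or a psychiatrist for
#' nerves, anxiety, tension or depression (fields 2090 / 2100). Any missing
#' input makes the status missing.
#'
#' @param ever_depressed,ever_disinterested Logical or 0/1 vectors.
#' @param dur_depressed,dur_disinterest Longest episode duration in weeks
#'   (0 for subjects without an episode).
#' @param seen_gp,seen_psych Logical or 0/1 vectors.
#' @return Integer 0/1 vector, `NA` where any input is missing.
#' @export
probable_depression_status <- function(ever_depressed, ever_disinterested,
                                       dur_depressed, dur_disinterest,
                                       seen_gp, seen_psych) {
  n <- length(ever_depressed)
  args <- list(ever_depressed, ever_disinterested, dur_depressed,
               dur_disinterest, seen_gp, seen_psych)
  assert_that("all six inputs must have equal length" =
                all(lengths(args) == n))
  ever <- (as.numeric(ever_depressed) > 0) | (as.numeric(ever_disinterested) > 0)
  week <- (as.numeric(dur_depressed) >= 1) | (as.numeric(dur_disinterest) >= 1)
  help <- (as.numeric(seen_gp) > 0) | (as.numeric(seen_psych) > 0)
  out <- as.integer(ever & week & help)
  # strict missingness: the status is defined only when all six fields are
  # observed (matching the cohort rule that drops incomplete mental health)
  missing_any <- Reduce(`|`, lapply(args, is.na))
  out[missing_any] <- NA_integer_
  out
}

#' Late-onset depression flag
#'
#' Subjects whose self-reported first depressive episode occurred at age 60
#' or older (field 20433) are flagged for exclusion; late-onset depression
#' carries distinct brain correlates and risk factors. A missing onset age
#' is no evidence of late onset and yields 0.
#'
#' @param age_first_episode Age in years at first episode, `NA` if never
#'   depressed or not asked.
#' @return Integer 0/1 vector.
#' @export
late_onset_flag <- function(age_first_episode) {
  x <- as.numeric(age_first_episode)
  if (any(x < 0, na.rm = TRUE)) abort("negative age at first episode")
  out <- as.integer(x >= 60)
  out[is.na(x)] <- 0L
  out
}

#' Cronbach's alpha internal consistency
#'
#' `alpha = k/(k-1) * (1 - sum of item variances / variance of the item
#' sum)`, with sample variances (n-1 denominator). Rows with any missing
#' item are dropped before computation.
#'
#' @param item_matrix Subjects x items data frame or matrix, >= 2 items and
#'   >= 3 complete rows.
#' @return Alpha as a single numeric value.
#' @export
cronbach_alpha <- function(item_matrix) {
  x <- as_numeric_matrix(item_matrix, "item_matrix")
  assert_that("need at least two items" = ncol(x) >= 2L)
  x <- x[complete.cases(x), , drop = FALSE]
  assert_that("need at least three complete rows" = nrow(x) >= 3L)
  k <- ncol(x)
  total_var <- var(rowSums(x))
  if (total_var <= 0) abort("total score has zero variance; alpha undefined")
  k / (k - 1) * (1 - sum(apply(x, 2L, var)) / total_var)
}

#' Compute all five mental-health summary scores for a phenotype table
#'
#' Looks up item columns through the table's column map and returns one row
#' per subject and timepoint with RDS-4, PHQ-9, GAD-7, N-12, probable
#' depression status and the late-onset flag. Scores whose items are
#' missing at a timepoint (e.g., online questionnaires at the second scan)
#' are missing, never imputed.
#'
#' @param tbl Phenotype table with an attached column map (see
#'   [simulate_cohort()], [read_phenotypes()]).
#' @param map Column map; defaults to the one attached to `tbl`.
#' @return A tibble: `subject_id`, `timepoint`, `rds4`, `phq9`, `gad7`,
#'   `n12`, `depression_status`, `late_onset`.
#' @export
score_phenotypes <- function(tbl, map = column_map(tbl)) {
  cols_for <- function(fields) {
    hit <- map$column[match(fields, map$field_id)]
    if (anyNA(hit)) {
      abort(paste0("column map lacks field(s): ",
                   paste(fields[is.na(hit)], collapse = ", ")))
    }
    hit
  }
  dep <- cols_for(depression_fields)
  tibble::tibble(
    subject_id = tbl$subject_id,
    timepoint = tbl$timepoint,
    rds4 = score_rds4(tbl[cols_for(rds4_fields)]),
    phq9 = score_sum_scale(tbl[cols_for(phq9_fields)], "phq9"),
    gad7 = score_sum_scale(tbl[cols_for(gad7_fields)], "gad7"),
    n12 = score_sum_scale(tbl[cols_for(n12_fields)], "n12"),
    depression_status = probable_depression_status(
      tbl[[dep[1]]], tbl[[dep[2]]], tbl[[dep[3]]],
      tbl[[dep[4]]], tbl[[dep[5]]], tbl[[dep[6]]]
    ),
    late_onset = late_onset_flag(tbl[[dep[7]]])
  )
}
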