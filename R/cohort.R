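#' Flag subjects for exclusion before matching
#'
#' Applies the pre-matching exclusion rules in their counting order: mean
#' head motion strictly greater than the threshold first, then any missing
#' mental-health summary measure, then probable late-onset depression
#' (first episode at 60 or older). Each subject receives the first
#' applicable reason.
#'
#' @param tbl Phenotype table (timepoint-1 rows are used).
#' @param scores Score table from [score_phenotypes()].
#' @param motion_limit Exclusion threshold on resting head motion in mm
#'   (default 0.2; exclusion is strict `>`).
#' @return Tibble: `subject_id`, `excluded`, `exclusion_reason` in
#'   `{motion, missing_mh, late_onset, none}`.
#' @export
apply_exclusions <- function(tbl, scores, motion_limit = 0.2) {
  if (!"head_motion_rest" %in% names(tbl)) {
    abort("head motion column `head_motion_rest` is required")
  }
  t1 <- dplyr::filter(tbl, .data$timepoint == 1L)
  s1 <- dplyr::filter(scores, .data$timepoint == 1L)
  s1 <- s1[match(t1$subject_id, s1$subject_id), ]
  motion <- t1$head_motion_rest > motion_limit
  missing_mh <- !complete.cases(
    s1[, c("rds4", "phq9", "gad7", "n12", "depression_status")]
  )
  late <- s1$late_onset == 1L
  reason <- dplyr::case_when(
    motion ~ "motion",
    missing_mh ~ "missing_mh",
    late ~ "late_onset",
    TRUE ~ "none"
  )
  tibble::tibble(
    subject_id = t1$subject_id,
    excluded = reason != "none",
    exclusion_reason = reason
  )
}

#' Greedy 1:1 exact matching of cases to controls
#'
#' Cases ("ever seen GP for nerves, anxiety, tension or depression") are
#' processed in seeded random order. For each case, candidate controls are
#' those with identical sex and integer age within `age_tolerance` years
#' (default exact); among candidates the one minimising the absolute head
#' motion difference is taken and removed from the pool, ties broken by
#' smallest subject ID. Cases with no candidate are left unmatched.
#'
#' @param data Tibble with columns `subject_id`, `case` (logical), `sex`,
#'   `age`, `motion`.
#' @param seed Integer seed controlling the case processing order.
#' @param age_tolerance Maximum |age difference| in integer years.
#' @return Tibble of pairs (`pair_id`, `case_id`, `control_id`), with the
#'   unmatched case IDs in `attr(, "unmatched")`.
#' @export
match_pairs <- function(data, seed = 1L, age_tolerance = 0L) {
  assert_that(
    "data needs subject_id, case, sex, age, motion columns" =
      all(c("subject_id", "case", "sex", "age", "motion") %in% names(data))
  )
  cases <- dplyr::filter(data, .data$case)
  controls <- dplyr::filter(data, !.data$case)
  if (nrow(controls) == 0L && nrow(cases) > 0L) {
    warn("empty control pool: all cases unmatched")
  }
  order_idx <- with_seed(seed, sample.int(max(nrow(cases), 1L)))
  pool <- controls
  out <- vector("list", nrow(cases))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[order_idx[i], ]
    cand <- which(pool$sex == cs$sex & abs(pool$age - cs$age) <= age_tolerance)
    if (length(cand) == 0L) next
    dmot <- abs(pool$motion[cand] - cs$motion)
    # minimal |delta motion|, ties broken by smallest subject_id
    best <- cand[order(dmot, pool$subject_id[cand])][1L]
    out[[i]] <- tibble::tibble(case_id = cs$subject_id,
                               control_id = pool$subject_id[best])
    pool <- pool[-best, ]
  }
  pairs <- dplyr::bind_rows(out)
  if (nrow(pairs)) {
    pairs <- dplyr::arrange(pairs, .data$case_id)
    pairs$pair_id <- sprintf("P%05d", seq_len(nrow(pairs)))
    pairs <- pairs[, c("pair_id", "case_id", "control_id")]
  } else {
    pairs <- tibble::tibble(pair_id = character(), case_id = character(),
                            control_id = character())
  }
  attr(pairs, "unmatched") <- setdiff(cases$subject_id, pairs$case_id)
  pairs
}

#' Split matched pairs into exploratory and confirmatory samples
#'
#' Pairs are split at the pair level so both members always land in the
#' same sample; approximately `frac_exploratory` of pairs (rounded down)
#' form the exploratory sample and the rest the confirmatory sample.
#'
#' @param pairs Pair table from [match_pairs()].
#' @param frac_exploratory Fraction of pairs assigned to the exploratory
#'   sample, in (0, 1); default 2/3.
#' @param seed Integer seed.
#' @return Tibble: `subject_id`, `group`, `pair_id`.
#' @export
split_samples <- function(pairs, frac_exploratory = 2 / 3, seed = 1L) {
  assert_that(
    "frac_exploratory must lie strictly between 0 and 1" =
      is.numeric(frac_exploratory) && frac_exploratory > 0 &&
        frac_exploratory < 1
  )
  n_pairs <- nrow(pairs)
  n_expl <- floor(frac_exploratory * n_pairs)
  expl <- with_seed(seed, sample.int(n_pairs, n_expl))
  grp <- ifelse(seq_len(n_pairs) %in% expl, "exploratory", "confirmatory")
  tidyr::pivot_longer(
    dplyr::mutate(pairs, group = grp),
    cols = c("case_id", "control_id"), values_to = "subject_id"
  )[, c("subject_id", "group", "pair_id")]
}

#' Build the full cohort assignment
#'
#' Reproduces the subject-flow of a matched case-control imaging study:
#' exclusions (motion, missing mental health, late onset), set-aside of the
#' two-timepoint test-retest sample, greedy exact matching of "seen GP"
#' cases to "never seen GP" controls among the remaining subjects, and a
#' pair-level exploratory/confirmatory split.
#'
#' @inheritParams apply_exclusions
#' @inheritParams match_pairs
#' @inheritParams split_samples
#' @return Tibble: `subject_id`, `group` in `{exploratory, confirmatory,
#'   retest, excluded}`, `pair_id`, `exclusion_reason` in `{motion,
#'   missing_mh, late_onset, unmatched, none}`.
#' @export
build_cohort <- function(tbl, scores, motion_limit = 0.2,
                         frac_exploratory = 2 / 3, seed = 1L,
                         age_tolerance = 0L) {
  excl <- apply_exclusions(tbl, scores, motion_limit)
  t1 <- dplyr::filter(tbl, .data$timepoint == 1L)
  eligible <- excl$subject_id[!excl$excluded]
  two_tp <- unique(tbl$subject_id[tbl$timepoint == 2L])
  retest <- intersect(eligible, two_tp)
  pool_ids <- setdiff(eligible, retest)
  pool <- dplyr::transmute(
    dplyr::filter(t1, .data$subject_id %in% pool_ids),
    subject_id = .data$subject_id, case = .data$seen_gp == 1L,
    sex = .data$sex, age = .data$age, motion = .data$head_motion_rest
  )
  pairs <- match_pairs(pool, seed = seed, age_tolerance = age_tolerance)
  split <- split_samples(pairs, frac_exploratory, seed = seed)

  assignment <- tibble::tibble(subject_id = excl$subject_id) |>
    dplyr::left_join(split, by = "subject_id") |>
    dplyr::left_join(excl, by = "subject_id")
  assignment$group[assignment$subject_id %in% retest] <- "retest"
  unplaced <- is.na(assignment$group)
  assignment$group[unplaced] <- "excluded"
  assignment$exclusion_reason[unplaced &
                                assignment$exclusion_reason == "none"] <-
    "unmatched"
  structure(
    assignment[, c("subject_id", "group", "pair_id", "exclusion_reason")],
    class = c("cohort_assignment", class(assignment))
  )
}

#' Subject-flow report for a cohort assignment
#'
#' @param assignment Output of [build_cohort()].
#' @return Tibble of stages and subject counts, mirroring an inclusion
#'   flowchart.
#' @export
cohort_flow <- function(assignment) {
  n0 <- nrow(assignment)
  reason <- assignment$exclusion_reason
  tibble::tibble(
    stage = c("available", "excluded_motion", "excluded_missing_mh",
              "excluded_late_onset", "retest_sample", "unmatched",
              "exploratory", "confirmatory"),
    n = c(
      n0, sum(reason == "motion"), sum(reason == "missing_mh"),
      sum(reason == "late_onset"), sum(assignment$group == "retest"),
      sum(reason == "unmatched"),
      sum(assignment$group == "exploratory"),
      sum(assignment$group == "confirmatory")
    )
  )
}
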