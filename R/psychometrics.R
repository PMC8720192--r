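#' Spearman rank correlation with t-approximation p value
#'
#' Ranks use average ranks for ties; the two-sided p value comes from the
#' t approximation `t = rho * sqrt((n-2) / (1-rho^2))`.
#'
#' @param x,y Paired score vectors; incomplete pairs are dropped.
#' @return One-row tibble: `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  assert_that("need at least 4 complete pairs" = n >= 4L)
  if (sd(x) == 0 || sd(y) == 0) {
    abort("constant input: Spearman correlation undefined")
  }
  rho <- cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) {
    0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  tibble::tibble(rho = rho, p_value = p, n = n)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Sup-distance between the two empirical CDFs with the two-sided
#' asymptotic p value `p = 2 * sum_k (-1)^(k-1) exp(-2 k^2 t^2)` at
#' `t = sqrt(n_a n_b / (n_a + n_b)) D`, summed to machine convergence.
#'
#' @param a,b Score samples (non-empty; NAs dropped).
#' @return One-row tibble: `statistic`, `p_value`, `n_a`, `n_b`.
#' @export
ks_compare <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  assert_that("both samples must be non-empty" =
                length(a) > 0L && length(b) > 0L)
  res <- suppressWarnings(ks.test(a, b, exact = FALSE))
  d <- unname(res$statistic)
  t_stat <- sqrt(length(a) * length(b) / (length(a) + length(b))) * d
  tibble::tibble(statistic = d, p_value = kolmogorov_p(t_stat),
                 n_a = length(a), n_b = length(b))
}

# two-sided Kolmogorov limit tail probability, alternating series summed
# until the increment is below machine precision
kolmogorov_p <- function(t_stat) {
  if (t_stat < 1e-6) return(1)
  total <- 0
  for (k in seq_len(10000L)) {
    term <- (-1)^(k - 1) * exp(-2 * k^2 * t_stat^2)
    total <- total + term
    if (abs(term) < 1e-18) break
  }
  min(max(2 * total, 0), 1)
}

#' Mid-percentile rank of a score within a sample
#'
#' The observed-score equating convention for discrete scores:
#' `100 * (P(X < s) + 0.5 * P(X = s))`.
#'
#' @param scores Non-empty sample of integer scores.
#' @param s Score(s) to rank.
#' @return Percentiles in `[0, 100]`, vectorized over `s`.
#' @export
percentile_rank <- function(scores, s) {
  scores <- scores[!is.na(scores)]
  assert_that("sample must be non-empty" = length(scores) > 0L)
  vapply(s, function(si) {
    100 * (mean(scores < si) + 0.5 * mean(scores == si))
  }, numeric(1))
}

#' Equipercentile linking between two score scales
#'
#' For each attainable source score, its mid-percentile rank in the source
#' sample is mapped to the target scale by linear interpolation of the
#' target's score-to-percentile step function; extrapolation is clamped to
#' the target's attained range. Self-linking is the identity on attained
#' scores, and the mapped curve is monotone non-decreasing.
#'
#' @param source_sample,target_sample Integer score samples.
#' @return A `linking_table` tibble: `source_score`, `source_percentile`,
#'   `mapped_score`, `target_percentile`.
#' @export
equipercentile_link <- function(source_sample, target_sample) {
  src <- source_sample[!is.na(source_sample)]
  tgt <- target_sample[!is.na(target_sample)]
  assert_that("both samples must be non-empty" =
                length(src) > 0L && length(tgt) > 0L)
  tgt_grid <- sort(unique(tgt))
  if (length(tgt_grid) < 2L) {
    abort("degenerate target sample: a single attained score cannot be linked")
  }
  src_grid <- sort(unique(src))
  p_src <- percentile_rank(src, src_grid)
  p_tgt <- percentile_rank(tgt, tgt_grid)
  mapped <- approx(p_tgt, tgt_grid, xout = p_src, rule = 2, ties = "ordered")$y
  out <- tibble::tibble(
    source_score = src_grid,
    source_percentile = p_src,
    mapped_score = mapped,
    target_percentile = percentile_rank(tgt, round(mapped))
  )
  class(out) <- c("linking_table", class(out))
  out
}

#' Rank correlation as a function of measurement latency
#'
#' Groups subject pairs by the (absolute, by default) number of days
#' between the two measurements, and reports the Spearman correlation in
#' every bin holding at least `min_n` subjects.
#'
#' @param x,y Paired scores (e.g., scan-day and online questionnaires).
#' @param latency Signed days between the two measurements, same length.
#' @param bin_width Bin width in days.
#' @param min_n Minimum subjects per reported bin (default 20).
#' @param absolute Bin on |latency| (default) or on signed latency.
#' @return Tibble: `bin_lo`, `bin_hi`, `bin_mid`, `n`, `rho`, `p_value`.
#' @export
latency_binned_correlation <- function(x, y, latency, bin_width = 250,
                                       min_n = 20L, absolute = TRUE) {
  keep <- complete.cases(x, y, latency)
  x <- x[keep]; y <- y[keep]
  lat <- if (absolute) abs(latency[keep]) else latency[keep]
  lo0 <- if (absolute) 0 else floor(min(lat) / bin_width) * bin_width
  bin <- floor((lat - lo0) / bin_width)
  bin[lat == max(lat)] <- floor((max(lat) - lo0) / max(bin_width, 1e-9))
  out <- purrr::map_dfr(sort(unique(bin)), function(b) {
    idx <- bin == b
    if (sum(idx) < min_n) return(NULL)
    sp <- spearman_cor(x[idx], y[idx])
    tibble::tibble(
      bin_lo = lo0 + b * bin_width, bin_hi = lo0 + (b + 1) * bin_width,
      bin_mid = lo0 + (b + 0.5) * bin_width,
      n = sum(idx), rho = sp$rho, p_value = sp$p_value
    )
  })
  if (nrow(out) == 0L) warn("all latency bins hold fewer than min_n subjects")
  out
}

#' Apply survey quality filters
#'
#' Removes participants who failed an attention check, then participants
#' who completed a questionnaire session faster than the minimum plausible
#' duration (default 172.5 s, i.e., 2.5 s per question). Filtering is at
#' the participant level: failing at either timepoint removes the subject.
#'
#' @param tbl Survey table from [simulate_survey_retest()] (columns
#'   `subject_id`, `attention_passed`, `duration_seconds`).
#' @param min_duration Minimum questionnaire duration in seconds.
#' @return Filtered tibble; exclusion counts in `attr(, "filter_counts")`.
#' @export
filter_survey <- function(tbl, min_duration = 172.5) {
  assert_that(
    "survey table needs subject_id, attention_passed, duration_seconds" =
      all(c("subject_id", "attention_passed", "duration_seconds") %in%
            names(tbl))
  )
  per_subject <- dplyr::summarise(
    dplyr::group_by(tbl, .data$subject_id),
    attention_ok = all(.data$attention_passed),
    fast = any(.data$duration_seconds < min_duration),
    .groups = "drop"
  )
  n_total <- nrow(per_subject)
  failed <- per_subject$subject_id[!per_subject$attention_ok]
  fast <- per_subject$subject_id[per_subject$attention_ok & per_subject$fast]
  keep <- setdiff(per_subject$subject_id, c(failed, fast))
  out <- dplyr::filter(tbl, .data$subject_id %in% keep)
  attr(out, "filter_counts") <- tibble::tibble(
    n_input = n_total, n_attention_fail = length(failed),
    n_too_fast = length(fast), n_retained = length(keep)
  )
  attr(out, "column_map") <- attr(tbl, "column_map")
  out
}

#' Pairwise Spearman correlations among summary measures
#'
#' @param scores Tibble of summary scores (numeric columns only are used).
#' @return Tibble in long form: `measure_1`, `measure_2`, `rho`, `p_value`.
#' @export
score_comparison_matrix <- function(scores) {
  num <- scores[vapply(scores, is.numeric, logical(1))]
  nm <- names(num)
  combs <- utils::combn(nm, 2L)
  purrr::map_dfr(seq_len(ncol(combs)), function(i) {
    a <- combs[1L, i]; b <- combs[2L, i]
    sp <- spearman_cor(num[[a]], num[[b]])
    tibble::tibble(measure_1 = a, measure_2 = b,
                   rho = sp$rho, p_value = sp$p_value, n = sp$n)
  })
}
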