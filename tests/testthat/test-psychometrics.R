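test_that("spearman is rank-invariant and matches the tie-aware oracle", {
  x <- c(-2, -1, 0.5, 1, 3, 7)
  expect_equal(spearman_cor(x, x^3)$rho, 1, tolerance = 1e-12)
  expect_equal(spearman_cor(x, -x)$rho, -1, tolerance = 1e-12)
  hand_x <- c(1, 2, 2, 3, 4, 4, 4, 5)
  hand_y <- c(2, 1, 3, 3, 5, 4, 6, 6)
  got <- spearman_cor(hand_x, hand_y)
  want <- oracle_spearman(hand_x, hand_y)
  expect_equal(got$rho, want$rho, tolerance = 1e-12)
  expect_equal(got$p_value, want$p, tolerance = 1e-12)
  set.seed(2)
  for (i in 1:10) {
    a <- sample(0:8, 25, TRUE)
    b <- a + sample(0:5, 25, TRUE)
    got <- spearman_cor(a, b)
    want <- oracle_spearman(a, b)
    expect_equal(got$rho, want$rho, tolerance = 1e-10)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
  }
  expect_error(spearman_cor(rep(1, 10), rnorm(10)), "constant")
  expect_error(spearman_cor(1:3, 3:1), "4 complete pairs")
})

test_that("KS statistic equals the brute-force maximal CDF gap", {
  expect_equal(ks_compare(1:20, 1:20)$statistic, 0)
  expect_equal(ks_compare(1:10, 101:110)$statistic, 1)
  set.seed(3)
  for (i in 1:10) {
    a <- sample(0:12, 20, TRUE)
    b <- sample(0:12, 20, TRUE) + sample(0:2, 1)
    got <- ks_compare(a, b)
    want <- oracle_ks(a, b)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
    # sanity agreement with R's asymptotic implementation, whose internal
    # series truncates its terms at 1e-6
    r_p <- suppressWarnings(ks.test(a, b, exact = FALSE))$p.value
    expect_equal(got$p_value, r_p, tolerance = 1e-4)
  }
})

test_that("KS statistic is invariant under a common monotone transform", {
  set.seed(4)
  a <- rlnorm(40)
  b <- rlnorm(35) * 1.5
  raw <- ks_compare(a, b)$statistic
  expect_equal(ks_compare(log(a), log(b))$statistic, raw, tolerance = 1e-12)
  expect_equal(ks_compare(sqrt(a), sqrt(b))$statistic, raw, tolerance = 1e-12)
})

test_that("mid-percentile ranks follow the counting definition", {
  expect_equal(percentile_rank(c(4, 4, 5, 6), 4), 25)
  expect_equal(percentile_rank(1:5, 3), 50)  # unique median of odd n
  expect_equal(percentile_rank(c(2, 3, 4), 0), 0)  # below all data
  set.seed(5)
  for (i in 1:10) {
    s <- sample(0:10, 30, TRUE)
    pt <- sample(0:10, 1)
    expect_equal(percentile_rank(s, pt), oracle_percentile(s, pt),
                 tolerance = 1e-12)
  }
})

test_that("equipercentile self-linking is the identity on attained
           scores", {
  set.seed(6)
  s <- sample(4:16, 300, TRUE, prob = 13:1)
  link <- equipercentile_link(s, s)
  expect_equal(link$mapped_score, link$source_score, tolerance = 1e-10)
})

test_that("linking a scale to its own linear transform recovers the line", {
  set.seed(7)
  s <- sample(0:12, 500, TRUE, prob = rev(seq(0.5, 3, length.out = 13)))
  link <- equipercentile_link(s, 2 * s + 1)
  expect_equal(link$mapped_score, 2 * link$source_score + 1,
               tolerance = 1e-10)
})

test_that("linked curves are monotone for skewed scores across many
           seeds", {
  for (seed in 1:100) {
    set.seed(seed)
    src <- sample(4:16, 120, TRUE, prob = 13:1)
    tgt <- sample(0:27, 150, TRUE, prob = rev(seq_len(28)))
    link <- equipercentile_link(src, tgt)
    expect_true(all(diff(link$mapped_score) >= -1e-12))
    expect_true(all(link$mapped_score >= min(tgt) - 1e-12 &
                      link$mapped_score <= max(tgt) + 1e-12))
  }
  expect_error(equipercentile_link(1:10, rep(3, 10)), "degenerate")
})

test_that("round-trip linking returns within one score unit on dense
           samples", {
  set.seed(8)
  a <- sample(4:16, 2000, TRUE, prob = 13:1)
  b <- sample(0:27, 2000, TRUE, prob = rev(seq(1, 4, length.out = 28)))
  ab <- equipercentile_link(a, b)
  ba <- equipercentile_link(b, a)
  round_trip <- approx(ba$source_score, ba$mapped_score,
                       xout = ab$mapped_score, rule = 2)$y
  expect_lt(max(abs(round_trip - ab$source_score)), 1)
})

test_that("latency-binned correlation reduces to plain spearman for one
           bin and decays with latency on generated data", {
  set.seed(9)
  x <- rnorm(100); y <- x + rnorm(100)
  lat <- rep(3, 100)  # zero-width latency range: a single bin
  out <- latency_binned_correlation(x, y, lat, bin_width = 250)
  expect_identical(nrow(out), 1L)
  expect_equal(out$rho, spearman_cor(x, y)$rho, tolerance = 1e-12)

  tbl <- shared_cohort()
  sc <- shared_scores()
  t1 <- tbl[tbl$timepoint == 1L, ]
  s1 <- sc[sc$timepoint == 1L, ]
  s1 <- s1[match(t1$subject_id, s1$subject_id), ]
  bins <- latency_binned_correlation(s1$rds4, s1$phq9, t1$latency_days,
                                     bin_width = 400)
  expect_gte(nrow(bins), 2L)
  # early bins correlate more strongly than late bins
  expect_gt(bins$rho[1], bins$rho[nrow(bins)])

  expect_warning(
    empty <- latency_binned_correlation(x[1:5], y[1:5], lat[1:5],
                                        bin_width = 10),
    "fewer than"
  )
  expect_identical(nrow(empty), 0L)
})

test_that("survey quality filters drop attention failures then fast
           completions at 172.5 s", {
  svy <- simulate_survey_retest(n = 60, seed = 11, n_attention_fail = 2,
                                n_too_fast = 5)
  kept <- filter_survey(svy)
  counts <- attr(kept, "filter_counts")
  expect_identical(counts$n_input, 60L)
  expect_identical(counts$n_attention_fail, 2L)
  expect_identical(counts$n_too_fast, 5L)
  expect_identical(counts$n_retained, 53L)
  expect_identical(dplyr::n_distinct(kept$subject_id), 53L)
  expect_true(all(kept$attention_passed))
  expect_true(all(kept$duration_seconds >= 172.5))
})
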