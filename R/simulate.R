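#' Configuration for the synthetic cohort generator
#'
#' Collects and validates all generator knobs. The defaults are the study
#' conditions the package is developed and tested under: a population
#' sample with a planted low-rank brain-behaviour mode, structural imaging
#' more reliable than functional, online questionnaires acquired up to
#' three years away from the scan, and sparse missingness confined to
#' structural/task IDPs.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Integer seed; a fixed seed yields a bit-identical table.
#' @param effect_r Planted first canonical correlation between the IDP
#'   block and the five summary scores, in `[0, 1)`.
#' @param n_idp_per_modality Named integer vector, IDP count per modality
#'   tag (see [idp_modalities()]).
#' @param reliability_per_modality Named numeric vector, target two-year
#'   test-retest correlation per modality, each in `[0, 1]`.
#' @param frac_retest Fraction of subjects scanned at a second timepoint.
#' @param missing_rate Fraction of structural/task IDP cells set missing
#'   (missing completely at random, at timepoint-independent positions).
#' @param latency_days_range Integer interval for the signed offset between
#'   online questionnaire completion and scan day.
#' @param latency_decay_days E-folding time (days) of the latent affect
#'   autocorrelation that attenuates online measures at long latencies.
#' @param affect_stability,trait_stability Correlation of the state-affect
#'   and trait latents across the ~2-year rescan interval.
#' @param affect_trait_cor Correlation between the two latents.
#' @param confound_var Fraction of IDP variance contributed by confounds.
#' @param retest_interval_days Mean and SD (length 2) of the inter-scan
#'   interval in days.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 2000L,
                       seed = 1L,
                       effect_r = 0.3,
                       n_idp_per_modality = c(
                         amplitude = 10L, full_edge = 30L, partial_edge = 30L,
                         volume = 16L, area = 10L, thickness = 10L,
                         fa = 6L, md = 6L, t2star = 3L, wmh = 1L, task = 4L
                       ),
                       reliability_per_modality = c(
                         amplitude = 0.45, full_edge = 0.45,
                         partial_edge = 0.45, task = 0.45,
                         volume = 0.85, area = 0.85, thickness = 0.85,
                         fa = 0.85, md = 0.85, t2star = 0.85, wmh = 0.85
                       ),
                       frac_retest = 0.25,
                       missing_rate = 0.02,
                       latency_days_range = c(-1185L, 964L),
                       latency_decay_days = 1830,
                       affect_stability = 0.89,
                       trait_stability = 0.98,
                       affect_trait_cor = 0.6,
                       confound_var = 0.05,
                       retest_interval_days = c(824, 45)) {
  mods <- idp_modalities()$modality
  assert_that(
    "n_subjects must be a positive count" = is_count(n_subjects),
    "seed must be a single integer" = is_count(abs(seed) + 1),
    "effect_r must lie in [0, 1)" =
      is.numeric(effect_r) && effect_r >= 0 && effect_r < 1,
    "n_idp_per_modality must cover every modality with counts >= 1" =
      all(mods %in% names(n_idp_per_modality)) &&
        all(vapply(n_idp_per_modality, is_count, logical(1))),
    "reliability_per_modality must cover every modality with values in [0,1]" =
      all(mods %in% names(reliability_per_modality)) &&
        all(vapply(reliability_per_modality, is_fraction, logical(1))),
    "frac_retest must lie in [0, 1]" = is_fraction(frac_retest),
    "missing_rate must lie in [0, 1]" = is_fraction(missing_rate),
    "latency_days_range must be an interval" =
      length(latency_days_range) == 2L &&
        latency_days_range[1] <= latency_days_range[2],
    "stability parameters must lie in [0, 1]" =
      is_fraction(affect_stability) && is_fraction(trait_stability)
  )
  structure(
    list(
      n_subjects = as.integer(n_subjects), seed = as.integer(seed),
      effect_r = effect_r,
      n_idp_per_modality = vapply(n_idp_per_modality[mods], as.integer,
                                  integer(1)),
      reliability_per_modality = reliability_per_modality[mods],
      frac_retest = frac_retest, missing_rate = missing_rate,
      latency_days_range = as.integer(latency_days_range),
      latency_decay_days = latency_decay_days,
      affect_stability = affect_stability,
      trait_stability = trait_stability,
      affect_trait_cor = affect_trait_cor,
      confound_var = confound_var,
      retest_interval_days = retest_interval_days
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  n_subjects:", x$n_subjects, "  seed:", x$seed,
      "  effect_r:", x$effect_r, "\n")
  cat("  IDPs:", sum(x$n_idp_per_modality), "across",
      length(x$n_idp_per_modality), "modalities\n")
  cat("  frac_retest:", x$frac_retest, "  missing_rate:", x$missing_rate, "\n")
  invisible(x)
}

# graded-response items: equally spaced quantile cut-points on the latent
# propensity, shifted right by `shift` probits to reproduce the right-skewed
# score distributions seen in population samples
draw_items <- function(latent, n_items, n_levels, lambda, shift, base) {
  n <- length(latent)
  cuts <- qnorm(seq_len(n_levels - 1L) / n_levels) + shift
  out <- matrix(0L, n, n_items)
  for (j in seq_len(n_items)) {
    p <- lambda * latent + sqrt(1 - lambda^2) * rnorm(n)
    out[, j] <- base + as.integer(rowSums(outer(p, cuts, `>`)))
  }
  out
}

item_settings <- list(
  rds = list(n = 4L, levels = 4L, lambda = 0.70, shift = 0.9, base = 1L),
  phq = list(n = 9L, levels = 4L, lambda = 0.70, shift = 1.0, base = 0L),
  gad = list(n = 7L, levels = 4L, lambda = 0.70, shift = 1.0, base = 0L),
  n12 = list(n = 12L, levels = 2L, lambda = 0.65, shift = 0.52, base = 0L)
)

draw_scale <- function(latent, key) {
  s <- item_settings[[key]]
  draw_items(latent, s$n, s$levels, s$lambda, s$shift, s$base)
}

# modality-level loading plan: per-IDP planted-mode loading a, one latent
# factor per modality (shared structured noise) with per-IDP variance fvar
idp_plan <- function(config) {
  weights <- c(amplitude = 1.2, full_edge = 1.0, partial_edge = 1.2,
               volume = 0.8, area = 0.7, thickness = 0.7, fa = 0.9,
               md = 0.8, t2star = 0.7, wmh = 0.7, task = 1.0)
  counts <- config$n_idp_per_modality
  purrr::map_dfr(names(counts), function(m) {
    p <- counts[[m]]
    tibble::tibble(
      idp = sprintf("idp_%s_%02d", m, seq_len(p)),
      modality = m,
      a = 0.22 * weights[[m]],
      fvar = if (p >= 3L) 0.45 else 0
    )
  })
}

#' Simulate a phenotype table with planted brain-behaviour structure
#'
#' Generates a wide subject x timepoint table holding questionnaire items,
#' confounds and IDP columns, with the statistical structure the pipeline
#' assumes: a latent state-affect factor drives ordinal item responses
#' through a graded threshold model; the IDP block carries a rank-1
#' component calibrated so the population canonical correlation between the
#' IDP block and the five summary scores equals `effect_r`; confounds enter
#' the IDPs with known coefficients; a retest subset is rescanned about two
#' years later with per-modality test-retest correlations equal to
#' `reliability_per_modality`; structural/task IDP cells are missing
#' completely at random at timepoint-independent positions.
#'
#' The planted truth (latents, loadings, calibration constants) is attached
#' as `attr(tbl, "truth")` for validation; downstream stages never read it.
#'
#' @param config A [sim_config()].
#' @return A tibble with an attached column map (see [column_map()]).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  n <- config$n_subjects
  subject_id <- sprintf("S%05d", seq_len(n))

  ## --- confounds ---------------------------------------------------------
  site <- sample(c("siteA", "siteB", "siteC"), n, TRUE, prob = c(.4, .35, .25))
  sex <- rbinom(n, 1L, 0.34)                      # 1 = male
  age <- pmin(pmax(round(rnorm(n, 62, 7)), 45L), 82L)
  head_size <- rnorm(n, 1500, 100)
  head_motion_rest <- rlnorm(n, log(0.12), 0.45)
  head_motion_task <- rlnorm(n, log(0.12), 0.45)
  scan_date <- round(runif(n, 0, 1460))
  latency_days <- as.integer(round(runif(
    n, config$latency_days_range[1], config$latency_days_range[2]
  )))

  ## --- latent structure --------------------------------------------------
  z <- rnorm(n)                                   # state affect at scan day
  rho_wz <- config$affect_trait_cor
  w <- rho_wz * z + sqrt(1 - rho_wz^2) * rnorm(n) # trait neuroticism
  rho_l <- exp(-abs(latency_days) / config$latency_decay_days)
  z_online <- rho_l * z + sqrt(1 - rho_l^2) * rnorm(n)

  ## --- questionnaire items (timepoint 1) ---------------------------------
  rds_items <- draw_scale(z, "rds")
  n12_items <- draw_scale(w, "n12")
  phq_items <- draw_scale(z_online, "phq")
  gad_latent <- (z_online + w) / sqrt(2 + 2 * rho_wz * rho_l)
  gad_items <- draw_scale(gad_latent, "gad")

  ## --- lifetime depression fields ----------------------------------------
  liab <- 0.8 * (0.5 * z + 0.7 * w) / sqrt(0.25 + 0.49 + 0.7 * rho_wz) +
    0.6 * rnorm(n)
  ever_dep <- as.integer(0.9 * liab + sqrt(1 - 0.81) * rnorm(n) > qnorm(0.65))
  ever_dis <- as.integer(0.9 * liab + sqrt(1 - 0.81) * rnorm(n) > qnorm(0.70))
  dur_dep <- ifelse(ever_dep == 1L,
                    pmax(0L, round(rlnorm(n, log(4), 1))), 0L)
  dur_dis <- ifelse(ever_dis == 1L,
                    pmax(0L, round(rlnorm(n, log(3), 1))), 0L)
  seen_gp <- as.integer(0.9 * liab + sqrt(1 - 0.81) * rnorm(n) > qnorm(0.70))
  seen_psych <- as.integer(0.9 * liab + sqrt(1 - 0.81) * rnorm(n) > qnorm(0.88))
  onset <- rep(NA_real_, n)
  dep_idx <- which(ever_dep == 1L)
  onset[dep_idx] <- 18 + round(rbeta(length(dep_idx), 2, 5) *
                                 (age[dep_idx] - 18))

  ## --- planted canonical mode --------------------------------------------
  plan <- idp_plan(config)
  p_idp <- nrow(plan)
  mods <- unique(plan$modality)
  # per-IDP factor loadings (random sign and magnitude) and noise scales
  fload <- sqrt(plan$fvar * runif(p_idp, 0.7, 1.3)) *
    sample(c(-1, 1), p_idp, TRUE)
  fload[plan$fvar == 0] <- 0
  s2 <- 1 - plan$a^2 - fload^2
  if (any(s2 <= 0.05)) abort("IDP noise variance too small; adjust plan")

  # population covariance of the confound-free standardized IDP block and
  # the best attainable correlation R_x between an IDP combination and the
  # planted carrier t
  L <- matrix(0, p_idp, length(mods))
  for (k in seq_along(mods)) {
    rows <- plan$modality == mods[k]
    L[rows, k] <- fload[rows]
  }
  sigma_x <- tcrossprod(plan$a) + tcrossprod(L) + diag(s2)
  r_x <- sqrt(drop(crossprod(plan$a, solve(sigma_x, plan$a))))

  # summary-score block at timepoint 1, standardized; the carrier direction
  # v lies in its span, so the planted canonical correlation is c * R_x
  scores <- cbind(
    rds4 = rowSums(rds_items), phq9 = rowSums(phq_items),
    gad7 = rowSums(gad_items), n12 = rowSums(n12_items),
    status = as.numeric(probable_depression_status(
      ever_dep, ever_dis, dur_dep, dur_dis, seen_gp, seen_psych
    ))
  )
  keep <- apply(scores, 2L, sd) > 0
  if (!any(keep)) abort("degenerate score block; increase n_subjects")
  v <- rowMeans(scale(scores[, keep, drop = FALSE]))
  v <- as.numeric(scale(v))

  if (config$effect_r >= r_x) {
    abort(sprintf(
      "effect_r = %.3f cannot be realized: max attainable canonical correlation under the noise plan is %.3f",
      config$effect_r, r_x
    ))
  }
  cc <- config$effect_r / r_x
  t_carrier <- cc * v + sqrt(1 - cc^2) * rnorm(n)

  ## --- IDP block, both timepoints ----------------------------------------
  rel <- config$reliability_per_modality[plan$modality]
  if (any(rel < plan$a^2 + 1e-12)) {
    abort("reliability_per_modality below the planted-mode variance share")
  }
  rho_m <- (rel - plan$a^2) / (1 - plan$a^2)  # stability of non-signal part

  f1 <- matrix(rnorm(n * length(mods)), n)
  e1 <- matrix(rnorm(n * p_idp), n)
  base1 <- tcrossprod(t_carrier, plan$a) + f1 %*% t(L) +
    sweep(e1, 2L, sqrt(s2), "*")

  # confound contributions with fixed coefficients, shared across timepoints
  conf_std <- function(site, age, sex, head_size, motion_rest, motion_task,
                       date) {
    cbind(
      siteB = as.numeric(site == "siteB"), siteC = as.numeric(site == "siteC"),
      age = (age - 62) / 7, sex = sex - 0.34,
      head_size = (head_size - 1500) / 100,
      motion_rest = (motion_rest - 0.13) / 0.06,
      motion_task = (motion_task - 0.13) / 0.06,
      date = (date - 730) / 420
    )
  }
  C1 <- conf_std(site, age, sex, head_size, head_motion_rest,
                 head_motion_task, scan_date)
  gamma <- matrix(rnorm(ncol(C1) * p_idp, 0,
                        sqrt(config$confound_var / ncol(C1))),
                  ncol(C1), p_idp)
  idp1 <- base1 + C1 %*% gamma
  colnames(idp1) <- plan$idp

  ## --- retest subset ------------------------------------------------------
  n_retest <- round(config$frac_retest * n)
  retest_idx <- sort(sample.int(n, n_retest))
  interval <- pmin(pmax(round(rnorm(n_retest, config$retest_interval_days[1],
                                    config$retest_interval_days[2])),
                        700L), 980L)

  tp2 <- NULL
  if (n_retest > 0L) {
    rr <- retest_idx
    # per-IDP stability applies to factors and noise alike; realize it by
    # blending stable and fresh draws column-wise
    fnew <- matrix(rnorm(n * length(mods)), n)
    enew <- matrix(rnorm(n * p_idp), n)
    # factor stability: use the (count-weighted) mean rho of the modality
    rho_fac <- vapply(mods, function(m) mean(rho_m[plan$modality == m]),
                      numeric(1))
    f2 <- sweep(f1, 2L, rho_fac, `*`) +
      sweep(fnew, 2L, sqrt(1 - rho_fac^2), `*`)
    e2 <- sweep(e1, 2L, rho_m, `*`) + sweep(enew, 2L, sqrt(1 - rho_m^2), `*`)
    base2 <- tcrossprod(t_carrier, plan$a) + f2 %*% t(L) +
      sweep(e2, 2L, sqrt(s2), "*")

    age2 <- rep(NA_integer_, n)
    age2[rr] <- age[rr] + as.integer(floor(interval / 365.25))
    motion_rest2 <- rlnorm(n, log(0.12), 0.45)
    motion_task2 <- rlnorm(n, log(0.12), 0.45)
    date2 <- rep(NA_integer_, n)
    date2[rr] <- scan_date[rr] + interval
    C2 <- conf_std(site, ifelse(is.na(age2), age, age2), sex, head_size,
                   motion_rest2, motion_task2,
                   ifelse(is.na(date2), scan_date, date2))
    idp2 <- base2 + C2 %*% gamma
    colnames(idp2) <- plan$idp

    # scan-day items at timepoint 2 from evolved latents
    z2 <- config$affect_stability * z +
      sqrt(1 - config$affect_stability^2) * rnorm(n)
    w2 <- config$trait_stability * w +
      sqrt(1 - config$trait_stability^2) * rnorm(n)
    rds2 <- draw_scale(z2, "rds")
    n122 <- draw_scale(w2, "n12")

    tp2 <- list(rows = rr, idp = idp2[rr, , drop = FALSE],
                rds = rds2[rr, , drop = FALSE],
                n12 = n122[rr, , drop = FALSE],
                age = age2[rr], motion_rest = motion_rest2[rr],
                motion_task = motion_task2[rr], date = date2[rr],
                interval = interval)
  }

  ## --- missingness (structural/task only, timepoint-independent) ---------
  miss_cols <- which(modality_group(plan$modality) != "resting")
  miss_mask <- matrix(FALSE, n, p_idp)
  if (config$missing_rate > 0 && length(miss_cols) > 0L) {
    miss_mask[, miss_cols] <-
      matrix(runif(n * length(miss_cols)) < config$missing_rate,
             n, length(miss_cols))
    # never blank out an entire subject row within a PCA group
    for (g in c("structural", "task")) {
      gc <- which(modality_group(plan$modality) == g)
      full <- which(rowSums(miss_mask[, gc, drop = FALSE]) == length(gc))
      if (length(full)) miss_mask[full, gc[1]] <- FALSE
    }
    idp1[miss_mask] <- NA_real_
    if (!is.null(tp2)) {
      tp2$idp[miss_mask[tp2$rows, , drop = FALSE]] <- NA_real_
    }
  }

  ## --- assemble tibble ----------------------------------------------------
  item_cols <- function(rds, phq, gad, n12) {
    out <- cbind(rds, phq, gad, n12)
    colnames(out) <- c(names(rds4_fields), names(phq9_fields),
                       names(gad7_fields), names(n12_fields))
    tibble::as_tibble(out)
  }
  row1 <- dplyr::bind_cols(
    tibble::tibble(subject_id = subject_id, timepoint = 1L),
    item_cols(rds_items, phq_items, gad_items, n12_items),
    tibble::tibble(
      ever_depressed = ever_dep, ever_disinterested = ever_dis,
      dur_depressed_weeks = dur_dep, dur_disinterest_weeks = dur_dis,
      seen_gp = seen_gp, seen_psych = seen_psych, age_first_episode = onset,
      site = site, age = age, sex = sex, head_size = head_size,
      head_motion_rest = head_motion_rest, head_motion_task = head_motion_task,
      scan_date = scan_date, latency_days = latency_days,
      interval_days = NA_integer_
    ),
    tibble::as_tibble(idp1)
  )

  tbl <- row1
  if (!is.null(tp2)) {
    rr <- tp2$rows
    na_items <- matrix(NA_integer_, length(rr),
                       length(phq9_fields) + length(gad7_fields))
    row2 <- dplyr::bind_cols(
      tibble::tibble(subject_id = subject_id[rr], timepoint = 2L),
      item_cols(tp2$rds,
                matrix(NA_integer_, length(rr), 9L),
                matrix(NA_integer_, length(rr), 7L),
                tp2$n12),
      tibble::tibble(
        ever_depressed = ever_dep[rr], ever_disinterested = ever_dis[rr],
        dur_depressed_weeks = dur_dep[rr], dur_disinterest_weeks = dur_dis[rr],
        seen_gp = seen_gp[rr], seen_psych = seen_psych[rr],
        age_first_episode = onset[rr],
        site = site[rr], age = tp2$age, sex = sex[rr],
        head_size = head_size[rr],
        head_motion_rest = tp2$motion_rest, head_motion_task = tp2$motion_task,
        scan_date = as.integer(tp2$date), latency_days = latency_days[rr],
        interval_days = as.integer(tp2$interval)
      ),
      tibble::as_tibble(tp2$idp)
    )
    tbl <- dplyr::bind_rows(row1, row2)
  }

  attr(tbl, "column_map") <- build_column_map(plan)
  attr(tbl, "truth") <- list(
    z = z, w = w, t = t_carrier, v = v, c = cc, r_x = r_x,
    a = stats::setNames(plan$a, plan$idp), factor_loadings = fload,
    noise_var = s2, gamma = gamma, plan = plan,
    reliability = config$reliability_per_modality,
    config = config
  )
  class(tbl) <- c("phenotype_tbl", class(tbl))
  tbl
}

build_column_map <- function(plan) {
  item_map <- tibble::tibble(
    column = c(names(rds4_fields), names(phq9_fields), names(gad7_fields),
               names(n12_fields), names(depression_fields)),
    field_id = c(rds4_fields, phq9_fields, gad7_fields, n12_fields,
                 depression_fields),
    role = "item", modality = NA_character_
  )
  item_map$role[item_map$column %in% names(depression_fields)] <- "depression_field"
  conf_map <- tibble::tibble(
    column = c("site", "age", "sex", "head_size", "head_motion_rest",
               "head_motion_task", "scan_date"),
    field_id = NA_real_, role = "confound", modality = NA_character_
  )
  misc_map <- tibble::tibble(
    column = c("subject_id", "timepoint", "latency_days", "interval_days"),
    field_id = NA_real_, role = "meta", modality = NA_character_
  )
  idp_map <- tibble::tibble(
    column = plan$idp, field_id = NA_real_, role = "idp",
    modality = plan$modality
  )
  dplyr::bind_rows(misc_map, item_map, conf_map, idp_map)
}

#' Simulate a two-timepoint survey validation study
#'
#' Emulates an online validation study in which participants complete the
#' same questionnaires (RDS-4 and PHQ-9 style scales) twice, a short
#' interval apart, with per-subject completion time and attention-check
#' columns for exercising the quality filters (see [filter_survey()]).
#' A configurable share of item-propensity variance is a stable trait:
#' `stable_share = 1` reproduces identical responses (summary-score ICC 1),
#' `stable_share = 0` yields independent responses (ICC about 0).
#'
#' @param n Number of participants (>= 2).
#' @param interval_days Days between the two timepoints.
#' @param seed Integer seed.
#' @param stable_share Fraction of item-propensity variance shared across
#'   timepoints, in `[0, 1]`.
#' @param n_attention_fail Number of participants failing the attention
#'   checks.
#' @param n_too_fast Number of (attention-passing) participants completing
#'   faster than the minimum plausible duration.
#' @return A tibble, one row per participant and timepoint.
#' @export
simulate_survey_retest <- function(n = 134L, interval_days = 7L, seed = 1L,
                                   stable_share = 0.88,
                                   n_attention_fail = 3L, n_too_fast = 44L) {
  assert_that(
    "n must be >= 2" = is_count(n) && n >= 2,
    "stable_share must lie in [0, 1]" = is_fraction(stable_share),
    "exclusion counts exceed n" = n_attention_fail + n_too_fast <= n
  )
  with_seed(seed, {
    z <- rnorm(n)
    subject_id <- sprintf("M%04d", seq_len(n))
    draw_tp <- function(key) {
      s <- item_settings[[key]]
      # stable per-item propensity (includes latent + stable item part)
      q <- s$lambda * z + sqrt(1 - s$lambda^2) * matrix(rnorm(n * s$n), n)
      lapply(1:2, function(tp) {
        p <- sqrt(stable_share) * q +
          sqrt(1 - stable_share) * matrix(rnorm(n * s$n), n)
        cuts <- qnorm(seq_len(s$levels - 1L) / s$levels) + s$shift
        s$base + vapply(seq_len(s$n), function(j) {
          as.integer(rowSums(outer(p[, j], cuts, `>`)))
        }, integer(n))
      })
    }
    rds <- draw_tp("rds")
    phq <- draw_tp("phq")

    fail_idx <- sample.int(n, n_attention_fail)
    fast_pool <- setdiff(seq_len(n), fail_idx)
    fast_idx <- sample(fast_pool, n_too_fast)
    attention_passed <- !(seq_len(n) %in% fail_idx)
    duration <- round(rlnorm(n, log(420), 0.35))
    duration[fast_idx] <- round(runif(n_too_fast, 60, 172))
    duration <- pmax(duration, ifelse(seq_len(n) %in% fast_idx, 60, 180))

    rows <- purrr::map_dfr(1:2, function(tp) {
      items <- cbind(rds[[tp]], phq[[tp]])
      colnames(items) <- c(names(rds4_fields), names(phq9_fields))
      dplyr::bind_cols(
        tibble::tibble(subject_id = subject_id, timepoint = tp),
        tibble::as_tibble(items),
        tibble::tibble(
          duration_seconds = duration,
          attention_passed = attention_passed,
          interval_days = ifelse(tp == 2L, interval_days, 0L)
        )
      )
    })
    attr(rows, "column_map") <- tibble::tibble(
      column = c("subject_id", "timepoint",
                 names(rds4_fields), names(phq9_fields),
                 "duration_seconds", "attention_passed", "interval_days"),
      field_id = c(NA, NA, rds4_fields, phq9_fields, NA, NA, NA),
      role = c("meta", "meta", rep("item", 13L), "survey_qc", "survey_qc",
               "meta"),
      modality = NA_character_
    )
    rows
  })
}
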