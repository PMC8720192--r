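#' Run the full phenotype-to-IDP analysis pipeline
#'
#' Executes the whole workflow on a phenotype table: questionnaire scoring,
#' exclusions and matched cohort construction, per-sample confound
#' residualization, nearest-neighbour imputation, per-group PCA, canonical
#' correlation analysis with permutation inference, averaged-UV loadings
#' with Bonferroni selection, out-of-sample replication, confirmatory
#' univariate effect sizes, test-retest reliability, and the psychometric
#' comparisons (rank correlations, KS tests, equipercentile links, latency
#' analysis, internal consistency).
#'
#' @param config A [sim_config()]; used to simulate the table when `tbl`
#'   is not supplied, and echoed into the provenance record.
#' @param tbl Optional phenotype table (with column map) to analyse instead
#'   of simulating one.
#' @param n_perm Permutations for CCA inference (default 2000).
#' @param variance_target PCA explained-variance target per group
#'   (default 0.5).
#' @param motion_limit Head-motion exclusion threshold in mm (default 0.2).
#' @param frac_exploratory Fraction of matched pairs in the exploratory
#'   sample (default 2/3).
#' @param k_impute Neighbours for imputation (default 1).
#' @param seed Seed for matching, splitting and permutation streams;
#'   defaults to `config$seed`.
#' @param out_dir Optional directory; when given, result tables are written
#'   as CSV/JSON with a provenance record.
#' @return An `mh_pipeline` list: `table`, `scores`, `assignment`, `flow`,
#'   `pca`, `cca`, `loadings`, `replication`, `effects`, `effects_summary`,
#'   `reliability`, `reliability_summary`, `psychometrics`, `provenance`.
#' @export
run_pipeline <- function(config = sim_config(), tbl = NULL, n_perm = 2000L,
                         variance_target = 0.5, motion_limit = 0.2,
                         frac_exploratory = 2 / 3, k_impute = 1L,
                         seed = NULL, out_dir = NULL) {
  seed <- seed %||% config$seed
  tbl <- tbl %||% simulate_cohort(config)
  map <- column_map(tbl)

  scores <- score_phenotypes(tbl, map)
  assignment <- build_cohort(tbl, scores, motion_limit = motion_limit,
                             frac_exploratory = frac_exploratory, seed = seed)
  flow <- cohort_flow(assignment)

  expl <- prepare_sample(tbl, scores, assignment, "exploratory", map,
                         k_impute)
  conf <- prepare_sample(tbl, scores, assignment, "confirmatory", map,
                         k_impute)

  ## per-group PCA on the exploratory sample; held-out samples are
  ## projected, never refit
  pca_models <- purrr::map(
    split(seq_len(ncol(expl$idps)), expl$groups),
    function(cols) {
      fit_pca_group(expl$idps[, cols, drop = FALSE],
                    group = expl$groups[cols[1]],
                    variance_target = variance_target)
    }
  )
  comp_of <- function(prep) {
    do.call(cbind, purrr::map(pca_models, function(m) {
      pca_project(m, prep$idps[, m$variables, drop = FALSE])
    }))
  }
  x_expl <- comp_of(expl)
  x_conf <- comp_of(conf)

  model <- fit_cca(x_expl, expl$y)
  model <- cca_permutation(x_expl, expl$y, n_perm = n_perm, seed = seed,
                           model = model)
  loadings <- uv_loadings(model, expl$idps, mode = 1L,
                          modality = expl$modality)
  replication <- cca_replicate(model, x_conf, conf$y)

  effects <- effect_size_table(
    conf$idps, as.data.frame(conf$y), conf$status, loadings,
    modality = setNames(conf$modality, colnames(conf$idps))
  )
  effects_summary <- if (nrow(effects)) effect_size_summary(effects) else NULL

  reliability <- retest_reliability(tbl, scores, assignment, map)

  psycho <- psychometric_report(tbl, scores, assignment, map)

  out <- structure(
    list(
      table = tbl, scores = scores, assignment = assignment, flow = flow,
      pca = pca_models, cca = model, loadings = loadings,
      replication = replication, effects = effects,
      effects_summary = effects_summary,
      reliability = reliability$table,
      reliability_summary = reliability$summary,
      psychometrics = psycho,
      provenance = list(
        package = "phenolink",
        version = as.character(utils::packageVersion("phenolink")),
        seed = seed, n_perm = n_perm, variance_target = variance_target,
        motion_limit = motion_limit, frac_exploratory = frac_exploratory,
        k_impute = k_impute, config = unclass(config)
      )
    ),
    class = "mh_pipeline"
  )
  if (!is.null(out_dir)) write_results(out, out_dir)
  out
}

# residualize, impute and collect one sample's blocks
prepare_sample <- function(tbl, scores, assignment, group, map, k_impute) {
  ids <- assignment$subject_id[assignment$group == group]
  t1 <- dplyr::filter(tbl, .data$timepoint == 1L, .data$subject_id %in% ids)
  s1 <- dplyr::filter(scores, .data$timepoint == 1L,
                      .data$subject_id %in% ids)
  s1 <- s1[match(t1$subject_id, s1$subject_id), ]
  imap <- idp_columns(map)
  idps <- as_numeric_matrix(t1[imap$column], "idps")
  design <- confound_design(t1)
  groups <- modality_group(imap$modality)
  idps_r <- residualize(idps, design)
  idps_r <- knn_impute(idps_r, k = k_impute, groups = groups)
  y_raw <- as_numeric_matrix(
    s1[, c("rds4", "phq9", "gad7", "n12", "depression_status")], "scores"
  )
  y <- residualize(y_raw, design)
  colnames(y) <- c("rds4", "phq9", "gad7", "n12", "depression_status")
  list(
    subject_id = t1$subject_id, idps = idps_r, groups = groups,
    modality = imap$modality, y = y, status = s1$depression_status,
    scores = s1, design = design, table = t1
  )
}

# deconfounded per-timepoint IDPs for the retest sample, then ICC variants
retest_reliability <- function(tbl, scores, assignment, map) {
  ids <- assignment$subject_id[assignment$group == "retest"]
  if (length(ids) < 3L) {
    return(list(table = NULL, summary = NULL))
  }
  imap <- idp_columns(map)
  per_tp <- purrr::map(1:2, function(tp) {
    tt <- dplyr::filter(tbl, .data$timepoint == tp,
                        .data$subject_id %in% ids)
    tt <- tt[match(ids, tt$subject_id), ]
    resid <- residualize(as_numeric_matrix(tt[imap$column], "idps"),
                         confound_design(tt))
    list(table = tt, resid = resid)
  })
  interval <- per_tp[[2]]$table$interval_days
  rds1 <- scores$rds4[match(paste(ids, 1L),
                            paste(scores$subject_id, scores$timepoint))]
  rds2 <- scores$rds4[match(paste(ids, 2L),
                            paste(scores$subject_id, scores$timepoint))]
  rds_change <- rds2 - rds1
  rel <- reliability_table(
    per_tp[[1]]$resid, per_tp[[2]]$resid, modality = imap$modality,
    interval = interval,
    rds_change = if (all(is.na(rds_change))) NULL else rds_change
  )
  list(table = rel, summary = reliability_summary(rel))
}

# score comparisons, KS by depression status, equipercentile links,
# latency-binned correlation and internal consistency, in the exploratory
# sample
psychometric_report <- function(tbl, scores, assignment, map) {
  ids <- assignment$subject_id[assignment$group == "exploratory"]
  t1 <- dplyr::filter(tbl, .data$timepoint == 1L, .data$subject_id %in% ids)
  s1 <- dplyr::filter(scores, .data$timepoint == 1L,
                      .data$subject_id %in% ids)
  s1 <- s1[match(t1$subject_id, s1$subject_id), ]
  cont <- s1[, c("rds4", "phq9", "gad7", "n12")]
  comparisons <- score_comparison_matrix(
    s1[, c("rds4", "phq9", "gad7", "n12", "depression_status")]
  )
  ks <- purrr::map_dfr(names(cont), function(mm) {
    res <- ks_compare(cont[[mm]][s1$depression_status == 1],
                      cont[[mm]][s1$depression_status == 0])
    dplyr::mutate(res, measure = mm, .before = 1L)
  })
  links <- list(
    rds4_to_phq9 = equipercentile_link(s1$rds4, s1$phq9),
    rds4_to_n12 = equipercentile_link(s1$rds4, s1$n12),
    n12_to_gad7 = equipercentile_link(s1$n12, s1$gad7)
  )
  latency <- latency_binned_correlation(s1$rds4, s1$phq9, t1$latency_days)
  item_cols <- function(fields) {
    map$column[match(fields, map$field_id)]
  }
  alphas <- tibble::tibble(
    measure = c("rds4", "n12"),
    alpha = c(cronbach_alpha(t1[item_cols(rds4_fields)]),
              cronbach_alpha(t1[item_cols(n12_fields)]))
  )
  list(comparisons = comparisons, ks_by_status = ks, links = links,
       latency = latency, alphas = alphas)
}

#' Write pipeline results to a directory
#'
#' Emits the assignment, flow report, canonical modes, loading table,
#' replication table, effect sizes with their modality summary, the
#' reliability table and summary, the linking tables, and a JSON provenance
#' record.
#'
#' @param result An `mh_pipeline` object.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(result, out_dir) {
  stopifnot(inherits(result, "mh_pipeline"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    if (!is.null(x)) readr::write_csv(x, file.path(out_dir, name))
  }
  w(result$assignment, "cohort_assignment.csv")
  w(result$flow, "cohort_flow.csv")
  w(generics::tidy(result$cca), "cca_modes.csv")
  w(result$loadings, "uv_loadings.csv")
  w(result$replication, "cca_replication.csv")
  w(result$effects, "effect_sizes.csv")
  w(result$effects_summary, "effect_sizes_by_modality.csv")
  w(result$reliability, "reliability.csv")
  w(result$reliability_summary, "reliability_by_modality.csv")
  w(result$psychometrics$comparisons, "score_comparisons.csv")
  w(result$psychometrics$ks_by_status, "ks_by_status.csv")
  w(result$psychometrics$latency, "latency_correlation.csv")
  w(result$psychometrics$alphas, "cronbach_alpha.csv")
  purrr::iwalk(result$psychometrics$links, function(lk, nm) {
    readr::write_csv(lk, file.path(out_dir, paste0("link_", nm, ".csv")))
  })
  jsonlite::write_json(result$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.mh_pipeline <- function(x, ...) {
  cat("<mh_pipeline>\n")
  print(x$flow)
  cat(sprintf("CCA: r1 = %.3f (perm p = %.4g); replication r1 = %.3f (p_bonf = %.3g)\n",
              x$cca$r[1], x$cca$p_perm[1], x$replication$r[1],
              x$replication$p_bonferroni[1]))
  cat(sprintf("%d of %d IDPs significant after Bonferroni\n",
              sum(x$loadings$significant), nrow(x$loadings)))
  invisible(x)
}
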