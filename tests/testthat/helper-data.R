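# shared fixtures built in code; the medium cohort is memoised because
# several test files exercise it read-only

.fixture_env <- new.env(parent = emptyenv())

shared_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- simulate_cohort(
      sim_config(n_subjects = 1200, seed = 42)
    )
  }
  .fixture_env$cohort
}

shared_scores <- function() {
  if (is.null(.fixture_env$scores)) {
    .fixture_env$scores <- score_phenotypes(shared_cohort())
  }
  .fixture_env$scores
}

# residualize + impute + per-group PCA + CCA on a generated table, the way
# the pipeline stages compose; returns the pieces tests need
cca_from_table <- function(tbl, ids = NULL, variance_target = 0.5,
                           models = NULL) {
  map <- column_map(tbl)
  t1 <- dplyr::filter(tbl, timepoint == 1L)
  if (!is.null(ids)) t1 <- t1[t1$subject_id %in% ids, ]
  imap <- map[map$role == "idp", ]
  design <- confound_design(t1)
  idps <- residualize(as.matrix(t1[imap$column]), design)
  idps <- knn_impute(idps, 1L, modality_group(imap$modality))
  sc <- score_phenotypes(t1, map)
  y <- residualize(
    as.matrix(sc[, c("rds4", "phq9", "gad7", "n12", "depression_status")]),
    design
  )
  grp <- modality_group(imap$modality)
  if (is.null(models)) {
    models <- lapply(unique(grp), function(g) {
      fit_pca_group(idps[, grp == g, drop = FALSE], g, variance_target)
    })
  }
  x <- do.call(cbind, lapply(models, function(m) {
    pca_project(m, idps[, m$variables, drop = FALSE])
  }))
  list(x = x, y = y, idps = idps, modality = imap$modality,
       models = models, scores = sc, design = design, table = t1)
}
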