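#' Write a phenotype table with its sidecar column map
#'
#' Writes the table as CSV or TSV (chosen from the file extension) and a
#' JSON sidecar holding the column map plus a provenance record (package
#' version, generator seed and configuration when the table came from
#' [simulate_cohort()]).
#'
#' @param tbl Phenotype table.
#' @param path Output file; `.tsv` writes tab-separated, anything else CSV.
#' @param sidecar Path for the JSON sidecar; default `<path>.map.json`.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(tbl, path, sidecar = paste0(path, ".map.json")) {
  map <- column_map(tbl)
  truth <- attr(tbl, "truth")
  prov <- list(
    package = "phenolink",
    version = as.character(utils::packageVersion("phenolink"))
  )
  if (!is.null(truth)) {
    cfg <- unclass(truth$config)
    prov$seed <- cfg$seed
    prov$config <- cfg
  }
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::write_tsv(tbl, path)
  } else {
    readr::write_csv(tbl, path)
  }
  jsonlite::write_json(
    list(columns = map, provenance = prov),
    sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  invisible(path)
}

#' Read a phenotype table and reattach its column map
#'
#' @param path CSV/TSV file written by [write_phenotypes()] (or a UKB-style
#'   extract whose sidecar maps columns to data-field IDs).
#' @param sidecar JSON sidecar path; default `<path>.map.json`.
#' @return A tibble with the column map attached.
#' @export
read_phenotypes <- function(path, sidecar = paste0(path, ".map.json")) {
  tbl <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  map <- tibble::as_tibble(side$columns)
  map$field_id <- as.numeric(map$field_id)
  missing_cols <- setdiff(map$column, names(tbl))
  if (length(missing_cols)) {
    abort(paste0("columns named in the sidecar are absent from the table: ",
                 paste(missing_cols, collapse = ", ")))
  }
  attr(tbl, "column_map") <- map
  attr(tbl, "provenance") <- side$provenance
  class(tbl) <- c("phenotype_tbl", class(tbl))
  tbl
}
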