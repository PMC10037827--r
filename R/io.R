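# Plain-text readers/writers for the formats the pipeline consumes:
# phenotype CSV, per-subject time-series TSV (time x region, header row of
# region names), per-seed structural map CSV (subject_id, seed, region,
# value), and square FC matrix CSVs.

#' Write a cohort to disk in the pipeline's plain-text formats
#'
#' Writes `phenotype.csv`, `nodes.csv`, `structural.csv` and one
#' `timeseries/<subject_id>.tsv` per subject under `dir`.
#'
#' @param cohort A `hippnet_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "hippnet_cohort"))
  dir.create(file.path(dir, "timeseries"), recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    phenotype = file.path(dir, "phenotype.csv"),
    nodes = file.path(dir, "nodes.csv"),
    structural = file.path(dir, "structural.csv")
  )
  readr::write_csv(cohort$subjects, paths["phenotype"])
  readr::write_csv(cohort$nodes, paths["nodes"])
  readr::write_csv(cohort$structural, paths["structural"])
  ts_paths <- vapply(names(cohort$timeseries), function(id) {
    p <- file.path(dir, "timeseries", paste0(id, ".tsv"))
    readr::write_tsv(tibble::as_tibble(cohort$timeseries[[id]]), p)
    p
  }, character(1))
  invisible(c(paths, ts_paths))
}

#' Read cohort inputs from disk
#'
#' Counterpart of [write_cohort()]: reads the phenotype table, node catalog,
#' structural maps and per-subject time series.
#'
#' @param dir Directory produced by [write_cohort()] (or hand-assembled in
#'   the same layout).
#' @return A list with `subjects`, `nodes`, `structural`, `timeseries`.
#' @export
read_cohort <- function(dir) {
  need <- file.path(dir, c("phenotype.csv", "nodes.csv", "structural.csv"))
  absent <- need[!file.exists(need)]
  if (length(absent) > 0) {
    stop_schema(paste0("missing input file(s): ", paste(absent, collapse = ", ")))
  }
  subjects <- readr::read_csv(need[1], show_col_types = FALSE)
  nodes <- readr::read_csv(need[2], show_col_types = FALSE)
  structural <- readr::read_csv(need[3], show_col_types = FALSE)
  ts_files <- list.files(file.path(dir, "timeseries"), pattern = "\\.tsv$",
                         full.names = TRUE)
  timeseries <- lapply(ts_files, function(p) {
    as.matrix(readr::read_tsv(p, show_col_types = FALSE))
  })
  names(timeseries) <- sub("\\.tsv$", "", basename(ts_files))
  timeseries <- timeseries[subjects$subject_id[subjects$subject_id %in% names(timeseries)]]
  list(subjects = subjects, nodes = nodes, structural = structural,
       timeseries = timeseries)
}

#' Write an FC matrix set as square CSV files
#'
#' @param fc A `hippnet_fc_set`.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_fc_matrices <- function(fc, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  invisible(vapply(names(fc), function(id) {
    p <- file.path(dir, paste0(id, ".csv"))
    m <- fc[[id]]
    df <- tibble::as_tibble(m)
    df <- tibble::add_column(df, region = rownames(m), .before = 1)
    readr::write_csv(df, p)
    p
  }, character(1)))
}

#' Read an FC matrix set written by [write_fc_matrices()]
#'
#' @param dir Directory of square CSV matrices (first column `region`).
#' @return A `hippnet_fc_set`.
#' @export
read_fc_matrices <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (length(files) == 0) stop_schema(paste0("no FC matrix CSVs under ", dir))
  out <- lapply(files, function(p) {
    df <- readr::read_csv(p, show_col_types = FALSE)
    m <- as.matrix(df[, -1])
    rownames(m) <- df[[1]]
    m
  })
  names(out) <- sub("\\.csv$", "", basename(files))
  structure(out, class = "hippnet_fc_set")
}
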