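#' Read a cohort manifest
#'
#' The manifest is a UTF-8 CSV with a header and one row per subject.
#' Required columns: `subject_id`, `group` (one of `HC`, `SCD`, `aMCI`),
#' `age` (years), `sex` (`F`/`M`), and the cognitive scores `mmse`, `gds`,
#' `lmt_immediate`, `lmt_delayed` (empty cells become `NA`, never sentinel
#' numbers).
#'
#' @param path Path to the manifest CSV.
#' @return A data.frame with one validated row per subject, in file order.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = TRUE)
  required <- c("subject_id", "group", "age", "sex",
                "mmse", "gds", "lmt_immediate", "lmt_delayed")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stopf("manifest %s is missing required column(s): %s",
          path, paste(missing, collapse = ", "))
  }
  df <- df[required]
  bad <- which(!df$group %in% c("HC", "SCD", "aMCI"))
  if (length(bad)) {
    stopf("manifest row %d has unknown group label '%s' (expected HC, SCD or aMCI)",
          bad[1], df$group[bad[1]])
  }
  bad_sex <- which(!df$sex %in% c("F", "M"))
  if (length(bad_sex)) {
    stopf("manifest row %d has unknown sex label '%s' (expected F or M)",
          bad_sex[1], df$sex[bad_sex[1]])
  }
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
  for (col in c("age", "mmse", "gds", "lmt_immediate", "lmt_delayed")) {
    df[[col]] <- num(df[[col]])
  }
  if (anyNA(df$age) || any(df$age <= 0)) {
    stopf("manifest column 'age' must be a positive number for every subject")
  }
  if (anyDuplicated(df$subject_id)) {
    stopf("duplicated subject_id in manifest: %s",
          df$subject_id[duplicated(df$subject_id)][1])
  }
  df
}

#' Write a cohort manifest
#' @param manifest Data.frame as returned by [read_manifest()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read one subject's parcellated time series
#'
#' Expects delimited text whose first row holds the region labels and whose
#' subsequent rows are timepoints.  The delimiter is chosen from the file
#' extension (`.csv` means comma, anything else tab).  Columns are reordered
#' to atlas order when the file's label set equals the atlas label set in a
#' different order; any other mismatch is an error listing the symmetric
#' difference.
#'
#' @param path Path to the time-series file.
#' @param atlas A [region_atlas()].
#' @param subject_id Subject identifier attached to the result (defaults to
#'   the file name without extension).
#' @return A `clubnet_ts` object: list with `values` (T x N numeric matrix,
#'   columns in atlas order), `region_labels`, `subject_id`.
#' @export
read_timeseries <- function(path, atlas = region_atlas(),
                            subject_id = sub("\\.[^.]+$", "", basename(path))) {
  if (!file.exists(path)) stopf("time-series file not found: %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character")
  labels <- colnames(df)
  extra <- setdiff(labels, atlas$labels)
  miss  <- setdiff(atlas$labels, labels)
  if (length(extra) || length(miss)) {
    stopf("time-series %s labels do not match the atlas; missing: {%s}; unexpected: {%s}",
          path, paste(miss, collapse = ", "), paste(extra, collapse = ", "))
  }
  m <- matrix(NA_real_, nrow(df), ncol(df))
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stopf("non-numeric value '%s' in %s at timepoint %d, region %s",
            df[[j]][i], path, i, labels[j])
    }
    m[, j] <- v
  }
  colnames(m) <- labels
  m <- m[, atlas$labels, drop = FALSE]
  ts_matrix(m, atlas$labels, subject_id)
}

#' Construct a time-series object
#'
#' @param values T x N numeric matrix (rows = timepoints).
#' @param region_labels Length-N character vector.
#' @param subject_id Subject identifier string.
#' @return A `clubnet_ts` object.
#' @export
ts_matrix <- function(values, region_labels = colnames(values),
                      subject_id = "subject") {
  values <- as.matrix(values)
  if (is.null(region_labels)) stopf("region labels are required")
  if (length(region_labels) != ncol(values)) {
    stopf("got %d labels for %d columns", length(region_labels), ncol(values))
  }
  if (nrow(values) < 3L) stopf("need at least 3 timepoints, got %d", nrow(values))
  if (!all(is.finite(values))) stopf("time series contains non-finite values")
  colnames(values) <- region_labels
  structure(list(values = values, region_labels = as.character(region_labels),
                 subject_id = subject_id),
            class = "clubnet_ts")
}

#' @export
print.clubnet_ts <- function(x, ...) {
  cat("<clubnet_ts> subject ", x$subject_id, ": ", nrow(x$values),
      " timepoints x ", ncol(x$values), " regions\n", sep = "")
  invisible(x)
}

#' Write one subject's time series as TSV
#' @param ts A `clubnet_ts` object.
#' @param path Output path (`.tsv`).
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  utils::write.table(format(ts$values, digits = 10, trim = TRUE,
                            scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the standard result-file set of a pipeline run
#'
#' Writes a deterministic file set into `out_dir`: `metrics.tsv`
#' (subject-level area-under-curve summaries of the global metrics),
#' `nodal_metrics.tsv`, `clubs.json` (rich club, diverse club and their
#' overlap, as atlas label strings), `strengths.tsv` and `stats.tsv`.
#' Missing bundle elements produce headers-only files so downstream tooling
#' always finds the same set.  Identical bundles give byte-identical files.
#'
#' @param results Result bundle, typically from [run_pipeline()]: a list
#'   with any of `metrics`, `nodal_metrics`, `clubs`, `strengths`, `stats`.
#' @param out_dir Output directory, created if absent.
#' @return Character vector of the paths written.
#' @export
write_results <- function(results, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  probe <- file.path(out_dir, ".clubnet-write-probe")
  ok <- tryCatch({ file.create(probe) }, warning = function(w) FALSE)
  if (!isTRUE(ok)) stopf("output directory not writable: %s", out_dir)
  unlink(probe)

  empty <- list(
    metrics = data.frame(subject_id = character(), group = character(),
                         metric = character(), auc = numeric()),
    nodal_metrics = data.frame(subject_id = character(), region = character(),
                               degree = numeric(), nodal_efficiency = numeric(),
                               nodal_clustering = numeric(), nodal_Lp = numeric(),
                               betweenness = numeric(), pc = numeric()),
    strengths = data.frame(subject_id = character(), group = character(),
                           criterion = character(), club_strength = numeric(),
                           feeder_strength = numeric(), local_strength = numeric()),
    stats = data.frame(metric = character(), contrast = character(),
                       statistic_name = character(), value = numeric(),
                       df1 = numeric(), df2 = numeric(), p_raw = numeric(),
                       p_bonferroni = numeric(), n = integer(),
                       covariates = character())
  )
  paths <- character()
  for (nm in names(empty)) {
    df <- results[[nm]]
    if (is.null(df) || !nrow(df)) df <- empty[[nm]]
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) formatC(x, digits = 12, format = "g"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
    paths <- c(paths, p)
  }
  clubs <- results$clubs
  if (is.null(clubs)) {
    clubs <- list(rich_club = character(), diverse_club = character(),
                  overlap = character())
  }
  pj <- file.path(out_dir, "clubs.json")
  jsonlite::write_json(clubs, pj, auto_unbox = FALSE, pretty = TRUE)
  c(paths, pj)
}

#' Read back a clubs.json written by [write_results()]
#' @param path Path to `clubs.json`.
#' @return Named list of character vectors of region labels.
#' @export
read_clubs <- function(path) {
  lapply(jsonlite::read_json(path), function(x) as.character(unlist(x)))
}
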