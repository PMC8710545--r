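# On-disk formats and shared domain types.
#
# All matrices travel as dense delimited text (TSV) so that runs are portable
# and diffable; region order is defined by the atlas table and enforced
# everywhere.  Region indices are 0-based internally only at the C++ boundary;
# user-facing outputs always use region names.

#' Construct a regional BOLD time-series object
#'
#' @param data numeric matrix, T rows (time points) by R columns (regions).
#' @param tr_seconds repetition time in seconds (positive).
#' @param subject_id subject identifier.
#' @param region_names optional character vector of length R; defaults to the
#'   column names of `data` or `region_1..region_R`.
#' @return an object of class `regional_timeseries` with elements `data`,
#'   `tr_seconds`, `subject_id`.
#' @export
regional_timeseries <- function(data, tr_seconds, subject_id = "subject",
                                region_names = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (anyNA(data) || any(!is.finite(data))) {
    bad <- which(!is.finite(data), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at row %d, column %d", bad[1L], bad[2L]))
  }
  stopifnot(is.numeric(tr_seconds), length(tr_seconds) == 1L, tr_seconds > 0)
  if (is.null(region_names)) {
    region_names <- colnames(data)
    if (is.null(region_names))
      region_names <- paste0("region_", seq_len(ncol(data)))
  }
  stopifnot(length(region_names) == ncol(data))
  colnames(data) <- region_names
  structure(list(data = data, tr_seconds = as.numeric(tr_seconds),
                 subject_id = as.character(subject_id)),
            class = "regional_timeseries")
}

#' @export
print.regional_timeseries <- function(x, ...) {
  cat(sprintf("regional_timeseries '%s': %d time points x %d regions, TR = %g s\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr_seconds))
  invisible(x)
}

#' Read a regional time-series matrix from delimited text
#'
#' Rows are time points, columns regions; an optional header row carries
#' region names.  Any missing, non-numeric or ragged cell is an error naming
#' its location.
#'
#' @param path path to a TSV/CSV file.
#' @param tr_seconds repetition time in seconds.
#' @param subject_id subject identifier (defaults to the file stem).
#' @return a [regional_timeseries()] object; column order as on disk.
#' @export
read_timeseries <- function(path, tr_seconds,
                            subject_id = sub("\\.[^.]*$", "", basename(path))) {
  mat <- .read_numeric_matrix(path, what = "time series")
  regional_timeseries(mat, tr_seconds = tr_seconds, subject_id = subject_id,
                      region_names = colnames(mat))
}

#' Write a regional time series to tab-delimited text
#'
#' Values are written with round-trip precision; [read_timeseries()] on the
#' result reproduces the data exactly.
#'
#' @param ts a [regional_timeseries()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "regional_timeseries"))
  data.table::fwrite(data.table::as.data.table(ts$data), path, sep = "\t")
  invisible(path)
}

# Shared reader: delimited numeric matrix with optional header, strict about
# ragged rows and non-numeric cells.
.read_numeric_matrix <- function(path, what = "matrix") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  dt <- tryCatch(
    data.table::fread(path, header = "auto", colClasses = "character",
                      data.table = TRUE, fill = FALSE),
    error = function(e) stop(sprintf("cannot parse %s file '%s': %s",
                                     what, path, conditionMessage(e))))
  header <- !all(grepl("^V[0-9]+$", names(dt)))
  m <- as.matrix(dt)
  num <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("%s file '%s': non-numeric or missing value at row %d, column %d%s",
                 what, path, bad[1L], bad[2L],
                 if (header) " (excluding header)" else ""))
  }
  if (header) colnames(num) <- names(dt)
  num
}

#' Construct a connectivity matrix object
#'
#' @param data R x R numeric matrix; must be symmetric to within 1e-10.  The
#'   diagonal is stored as zero and excluded from all downstream sums and
#'   vectorizations.
#' @param kind one of `"SC"`, `"FC"`, `"DFC_WINDOW"`, `"DFC_CENTROID"`.
#'   FC/dFC entries must lie in \[-1, 1\]; SC entries must be nonnegative.
#' @param region_names optional character vector of region names.
#' @return an object of class `conn_matrix` with elements `data` and `kind`.
#' @export
conn_matrix <- function(data, kind = c("SC", "FC", "DFC_WINDOW", "DFC_CENTROID"),
                        region_names = NULL) {
  kind <- match.arg(kind)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) != ncol(data)) stop("connectivity matrix must be square")
  if (max(abs(data - t(data))) > 1e-10) stop("connectivity matrix must be symmetric")
  diag(data) <- 0
  if (kind == "SC") {
    if (any(data < 0)) stop("SC entries must be nonnegative")
  } else {
    if (any(data < -1 - 1e-10) || any(data > 1 + 1e-10))
      stop(sprintf("%s entries must lie in [-1, 1]", kind))
    data <- pmin(pmax(data, -1), 1)
  }
  if (!is.null(region_names)) {
    stopifnot(length(region_names) == nrow(data))
    dimnames(data) <- list(region_names, region_names)
  }
  structure(list(data = data, kind = kind), class = "conn_matrix")
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("conn_matrix (%s): %d x %d\n", x$kind, nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' Read a connectivity matrix from delimited text
#'
#' The matrix must be square.  Asymmetry up to 1e-8 is repaired by averaging
#' with the transpose; larger asymmetry is an error.  A nonzero diagonal
#' (e.g., the self-correlation convention of 1) is zeroed with a message.
#'
#' @param path path to a delimited text file holding an R x R matrix.
#' @param kind matrix kind, as in [conn_matrix()].
#' @return a `conn_matrix`.
#' @export
read_conn_matrix <- function(path, kind = c("SC", "FC", "DFC_WINDOW", "DFC_CENTROID")) {
  kind <- match.arg(kind)
  m <- .read_numeric_matrix(path, what = "connectivity matrix")
  if (nrow(m) != ncol(m))
    stop(sprintf("connectivity matrix in '%s' is not square (%d x %d)",
                 path, nrow(m), ncol(m)))
  asym <- max(abs(m - t(m)))
  if (asym > 1e-8)
    stop(sprintf("matrix in '%s' is asymmetric (max |M - t(M)| = %.3g > 1e-8)",
                 path, asym))
  m <- (m + t(m)) / 2
  if (any(diag(m) != 0)) {
    message(sprintf("read_conn_matrix: zeroing nonzero diagonal in '%s'", path))
    diag(m) <- 0
  }
  conn_matrix(m, kind = kind, region_names = colnames(m))
}

#' Write a connectivity matrix to tab-delimited text
#'
#' @param m a [conn_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_conn_matrix <- function(m, path) {
  stopifnot(inherits(m, "conn_matrix"))
  data.table::fwrite(data.table::as.data.table(m$data), path, sep = "\t")
  invisible(path)
}

#' Read and validate a subject table
#'
#' Expected CSV columns: `subject_id`, `group` (HC/MS), `age`, `sex`, `race`,
#' `disease_duration`, `phenotype` (CIS/RRMS/PROG or NA), `spinal_lesion_cat`
#' (0/1/2), `edss`.  The disability label is derived from EDSS with the
#' threshold 2 (no disability below, evidence of disability at or above) and
#' checked for consistency if a `disability` column is present.
#'
#' @param path CSV path.
#' @return a `data.frame` with a derived `disability` column
#'   (`"NONE"`, `"EVIDENCE"`, or `NA` for HC).
#' @export
read_subjects <- function(path) {
  df <- as.data.frame(data.table::fread(path, data.table = FALSE))
  validate_subjects(df)
}

#' Validate a subject table and derive the disability label
#'
#' @param df a data.frame as described in [read_subjects()].
#' @return the validated data.frame with a consistent `disability` column.
#' @export
validate_subjects <- function(df) {
  required <- c("subject_id", "group", "age", "sex")
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("subject table missing columns: ", paste(miss, collapse = ", "))
  if (!all(df$group %in% c("HC", "MS")))
    stop("group must be 'HC' or 'MS'")
  if ("edss" %in% names(df)) {
    e <- df$edss[!is.na(df$edss)]
    if (any(e < 0 | e > 10 | (e * 2) %% 1 != 0))
      stop("edss must lie in [0, 10] in steps of 0.5")
    derived <- ifelse(df$group == "HC", NA_character_,
                      ifelse(df$edss < 2, "NONE", "EVIDENCE"))
  } else {
    derived <- ifelse(df$group == "HC", NA_character_, NA_character_)
  }
  if ("disability" %in% names(df)) {
    stored <- as.character(df$disability)
    stored[stored %in% c("NA", "")] <- NA_character_
    mism <- which(!is.na(stored) & !is.na(derived) & stored != derived)
    if (length(mism))
      stop("disability label inconsistent with EDSS threshold 2 for subject(s): ",
           paste(df$subject_id[mism], collapse = ", "))
  }
  df$disability <- derived
  hc <- df$group == "HC"
  if ("edss" %in% names(df) && any(hc & !is.na(df$edss)))
    stop("HC subjects must have missing EDSS")
  df
}

#' Write a subject table to CSV
#' @param df subject data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_subjects <- function(df, path) {
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read a region-to-network assignment table
#'
#' @param path CSV with columns `region_name` and `network`; row order defines
#'   the region order used throughout.
#' @return a data.frame of class `atlas_networks` with columns `region_name`,
#'   `network` (factor over the 9 canonical networks).
#' @export
read_atlas <- function(path) {
  df <- as.data.frame(data.table::fread(path, data.table = FALSE))
  stopifnot(all(c("region_name", "network") %in% names(df)))
  nets <- c("VIS", "SOM", "DAN", "VAN", "LIM", "FP", "DMN", "SUB", "CER")
  bad <- setdiff(unique(df$network), nets)
  if (length(bad)) stop("unknown network label(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(df$region_name)) stop("duplicate region names in atlas")
  df$network <- factor(df$network, levels = nets)
  class(df) <- c("atlas_networks", "data.frame")
  df
}

#' Default 86-region atlas with Yeo-7 + subcortex + cerebellum networks
#'
#' 68 cortical regions (34 per hemisphere, Desikan-Killiany) assigned to the
#' seven canonical cortical networks, plus 16 subcortical regions and the two
#' cerebellar hemispheres.
#'
#' @return an `atlas_networks` data.frame with 86 rows.
#' @export
default_atlas <- function() {
  read_atlas(system.file("extdata", "atlas86_networks.csv", package = "dynconn",
                         mustWork = TRUE))
}

#' Networks used by an atlas, in canonical order
#' @param atlas an `atlas_networks` data.frame.
#' @return character vector of network levels.
#' @export
atlas_network_levels <- function(atlas) levels(atlas$network)
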