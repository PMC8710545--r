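# Static connectivity feature builders: Pearson FC, node strength, pairwise
# vectorization, the SC edge-prevalence filter, and feature-table assembly.

#' Static functional connectivity from a regional time series
#'
#' Entry (i, j) is the Pearson correlation of regional time courses i and j
#' over the full scan; the diagonal is stored as zero.
#'
#' @param ts a [regional_timeseries()].
#' @return a [conn_matrix()] of kind `"FC"`.
#' @export
compute_fc <- function(ts) {
  stopifnot(inherits(ts, "regional_timeseries"))
  x <- ts$data
  if (nrow(x) < 3L) stop("need at least 3 time points for FC")
  v <- apply(x, 2L, var)
  if (any(v == 0))
    stop("zero-variance region(s): ",
         paste(colnames(x)[v == 0], collapse = ", "))
  r <- cor(x)
  diag(r) <- 0
  conn_matrix(r, kind = "FC", region_names = colnames(x))
}

#' Node strength of a connectivity matrix
#'
#' Strength of region i is the sum over j != i of f(m(i, j)), with
#' f(x) = max(x, 0) when `drop_negatives` (the convention for FC and dFC,
#' where negative weights are removed before summing) and f(x) = x otherwise
#' (SC, which is nonnegative anyway).
#'
#' @param m a [conn_matrix()].
#' @param drop_negatives drop negative entries before summing?
#' @return numeric vector of length R, named by region when available.
#' @export
node_strength <- function(m, drop_negatives = FALSE) {
  stopifnot(inherits(m, "conn_matrix"))
  x <- m$data
  if (drop_negatives) x <- pmax(x, 0)
  colSums(x)
}

#' Vectorize the strict upper triangle of a connectivity matrix
#'
#' Row-major order over pairs (i, j) with i < j, i.e. (1,2), (1,3), ...,
#' (1,R), (2,3), ...; length R(R-1)/2.  Names are `"A|B"` with A before B in
#' atlas order.
#'
#' @param m a [conn_matrix()] with R >= 2 regions.
#' @return named numeric vector of length `R * (R - 1) / 2`.
#' @export
vectorize_pairwise <- function(m) {
  stopifnot(inherits(m, "conn_matrix"))
  x <- m$data
  R <- nrow(x)
  if (R < 2L) stop("need at least 2 regions")
  idx <- which(upper.tri(x))
  # upper.tri indexes column-major; reorder to row-major over (i, j), i < j
  rows <- ((idx - 1L) %% R) + 1L
  cols <- ((idx - 1L) %/% R) + 1L
  ord <- order(rows, cols)
  v <- x[idx][ord]
  rn <- rownames(x)
  if (is.null(rn)) rn <- paste0("region_", seq_len(R))
  names(v) <- paste(rn[rows[ord]], rn[cols[ord]], sep = "|")
  v
}

#' Rebuild a symmetric matrix from a pairwise vector
#'
#' Inverse of [vectorize_pairwise()]; the diagonal is zero.
#'
#' @param v numeric vector of length R(R-1)/2 in row-major upper-triangle
#'   order.
#' @param R number of regions.
#' @param kind matrix kind for the result.
#' @param region_names optional region names.
#' @return a [conn_matrix()].
#' @export
devectorize_pairwise <- function(v, R, kind = "DFC_CENTROID", region_names = NULL) {
  stopifnot(length(v) == R * (R - 1) / 2)
  m <- matrix(0, R, R)
  m[t(upper.tri(m))] <- v   # row-major fill of the lower triangle's transpose
  m <- t(m)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  conn_matrix(m, kind = kind, region_names = region_names)
}

#' SC edge-prevalence filter over control subjects
#'
#' Keeps edge (i, j) iff it is nonzero in strictly more than half of the
#' control SC matrices; used to exclude likely tractography false positives
#' before univariate testing.
#'
#' @param sc_list list of control [conn_matrix()] objects of kind `"SC"`.
#' @return logical R x R matrix (TRUE = keep), symmetric with FALSE diagonal.
#' @export
sc_prevalence_filter <- function(sc_list) {
  if (length(sc_list) == 0L) stop("need at least one control SC matrix")
  stopifnot(all(vapply(sc_list, inherits, TRUE, "conn_matrix")))
  counts <- Reduce(`+`, lapply(sc_list, function(m) (m$data > 0) * 1))
  mask <- counts > length(sc_list) / 2
  diag(mask) <- FALSE
  mask
}

# One-hot encode categorical covariates, dropping the first level as
# reference; numeric covariates pass through.  Missing numeric values are
# mean-imputed (cohort mean) so ridge sees complete data.
.encode_covariates <- function(df, vars) {
  out <- list()
  for (v in vars) {
    x <- df[[v]]
    if (is.numeric(x)) {
      if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
      out[[v]] <- matrix(x, ncol = 1L, dimnames = list(NULL, v))
    } else {
      x <- as.character(x)
      x[is.na(x)] <- "missing"
      lev <- sort(unique(x))
      if (length(lev) > 1L) {
        cols <- vapply(lev[-1L], function(l) as.numeric(x == l),
                       numeric(length(x)))
        cols <- matrix(cols, nrow = length(x),
                       dimnames = list(NULL, paste0(v, "_", lev[-1L])))
        out[[v]] <- cols
      }
    }
  }
  if (length(out)) do.call(cbind, out) else
    matrix(numeric(0), nrow = nrow(df), ncol = 0L)
}

#' Assemble a model's feature table
#'
#' Concatenates the covariate block (demographics/clinical, one-hot encoded
#' categoricals with the first level as reference) with the connectome block
#' for the requested model.  Connectome column counts are R(R-1)/2 for
#' pairwise SC/FC, K x R(R-1)/2 for pairwise dFC, R for regional SC/FC,
#' K x R for regional dFC, and K + K^2 + 1 for the dFC-metrics model
#' (K dwell times, the full K x K transition matrix, and the transition
#' count).
#'
#' @param subjects subject data.frame (see [read_subjects()]); row order
#'   defines subject order.
#' @param inputs per-subject connectome inputs, a list parallel to
#'   `subjects$subject_id`: a `conn_matrix` for `PAIR_SC`/`PAIR_FC`/
#'   `REG_SC`/`REG_FC`; a list of K state-centroid `conn_matrix` objects for
#'   `PAIR_DFC`; a K x R `regional_dfc` matrix for `REG_DFC`; a
#'   [state_metrics()] result for `DFC_METRICS`.
#' @param model_tag one of `"PAIR_SC"`, `"PAIR_FC"`, `"PAIR_DFC"`,
#'   `"REG_SC"`, `"REG_FC"`, `"REG_DFC"`, `"DFC_METRICS"`.
#' @param atlas an `atlas_networks` data.frame; supplies region names.
#' @param task `"group"` (HC vs patient: covariates sex, age, race) or
#'   `"disability"` (patient subgroups: additionally disease duration,
#'   phenotype, spinal-lesion category).
#' @param K number of dFC states (required for dFC models).
#' @return an object of class `feature_table`: list with `subject_ids`,
#'   `feature_names`, `values` (n x p matrix), `model_tag`, `covariate_cols`,
#'   `connectome_cols`.
#' @export
build_feature_table <- function(subjects, inputs, model_tag, atlas,
                                task = c("group", "disability"), K = NULL) {
  task <- match.arg(task)
  tags <- c("PAIR_SC", "PAIR_FC", "PAIR_DFC", "REG_SC", "REG_FC", "REG_DFC",
            "DFC_METRICS")
  if (!model_tag %in% tags) stop("unknown model_tag: ", model_tag)
  n <- nrow(subjects)
  if (length(inputs) != n) {
    miss <- setdiff(subjects$subject_id, names(inputs))
    stop("missing connectome input for subject(s): ",
         paste(if (length(miss)) miss else "(count mismatch)", collapse = ", "))
  }
  rn <- atlas$region_name
  prefix <- sub("^(PAIR|REG)_", "", model_tag)

  conn <- switch(model_tag,
    PAIR_SC = , PAIR_FC = {
      rows <- lapply(inputs, vectorize_pairwise)
      m <- do.call(rbind, rows)
      colnames(m) <- paste(prefix, names(rows[[1L]]), sep = "|")
      m
    },
    PAIR_DFC = {
      stopifnot(!is.null(K))
      m <- do.call(rbind, lapply(inputs, function(cm_list) {
        stopifnot(length(cm_list) == K)
        unlist(lapply(cm_list, vectorize_pairwise), use.names = FALSE)
      }))
      base <- names(vectorize_pairwise(inputs[[1L]][[1L]]))
      colnames(m) <- as.vector(vapply(seq_len(K), function(k)
        paste0("dFC|state", k, "|", base), character(length(base))))
      m
    },
    REG_SC = {
      m <- do.call(rbind, lapply(inputs, node_strength, drop_negatives = FALSE))
      colnames(m) <- paste0("SCstr|", rn)
      m
    },
    REG_FC = {
      m <- do.call(rbind, lapply(inputs, node_strength, drop_negatives = TRUE))
      colnames(m) <- paste0("FCstr|", rn)
      m
    },
    REG_DFC = {
      stopifnot(!is.null(K))
      rows <- lapply(inputs, function(rd) as.vector(t(rd)))  # state-major
      m <- do.call(rbind, rows)
      colnames(m) <- as.vector(vapply(seq_len(K), function(k)
        paste0("dFCstr|state", k, "|", rn), character(length(rn))))
      # unvisited-state rows arrive as NA; impute cohort mean and flag
      if (anyNA(m)) {
        flagged <- which(apply(is.na(m), 1L, any))
        for (j in which(apply(is.na(m), 2L, any)))
          m[is.na(m[, j]), j] <- mean(m[, j], na.rm = TRUE)
        attr(m, "imputed_subjects") <- subjects$subject_id[flagged]
      }
      m
    },
    DFC_METRICS = {
      stopifnot(!is.null(K))
      rows <- lapply(inputs, function(sm) {
        c(sm$mean_dwell, as.vector(t(sm$transition_prob)), sm$n_transitions)
      })
      m <- do.call(rbind, rows)
      tn <- as.vector(t(outer(seq_len(K), seq_len(K), function(i, j)
        paste0("trans|state", i, "|state", j))))
      colnames(m) <- c(paste0("dwell|state", seq_len(K)), tn, "ntrans")
      m
    })

  cov_vars <- c("sex", "age", "race")
  if (task == "disability")
    cov_vars <- c(cov_vars, "disease_duration", "phenotype", "spinal_lesion_cat")
  cov_vars <- intersect(cov_vars, names(subjects))
  sub_cov <- subjects[cov_vars]
  if ("spinal_lesion_cat" %in% names(sub_cov))
    sub_cov$spinal_lesion_cat <- as.character(sub_cov$spinal_lesion_cat)
  covm <- .encode_covariates(sub_cov, cov_vars)

  values <- cbind(covm, conn)
  imputed <- attr(conn, "imputed_subjects")
  rownames(values) <- subjects$subject_id
  if (anyDuplicated(colnames(values))) stop("duplicate feature names")
  structure(list(subject_ids = subjects$subject_id,
                 feature_names = colnames(values),
                 values = values,
                 model_tag = model_tag,
                 covariate_cols = colnames(covm),
                 connectome_cols = colnames(conn),
                 imputed_subjects = imputed),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table (%s): %d subjects x %d features (%d covariate + %d connectome)\n",
              x$model_tag, nrow(x$values), ncol(x$values),
              length(x$covariate_cols), length(x$connectome_cols)))
  invisible(x)
}

#' Write a feature table as CSV with a metadata header line
#' @param ft a `feature_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  stopifnot(inherits(ft, "feature_table"))
  meta <- sprintf("# model_tag=%s n_subjects=%d n_covariate=%d n_connectome=%d",
                  ft$model_tag, nrow(ft$values), length(ft$covariate_cols),
                  length(ft$connectome_cols))
  writeLines(meta, path)
  df <- data.frame(subject_id = ft$subject_ids, ft$values,
                   check.names = FALSE)
  data.table::fwrite(df, path, append = TRUE, col.names = TRUE)
  invisible(path)
}
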