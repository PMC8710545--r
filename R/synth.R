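# Synthetic-cohort generator: regional BOLD series whose windowed
# correlation structure switches among K latent covariance states under a
# group-dependent Markov chain, sparse nonnegative SC matrices with
# group-dependent node-strength effects, and a demographics table.  All
# effects are configurable ground truth for parameter-recovery tests.

#' Synthetic-cohort configuration
#'
#' Defaults mirror the study conditions the pipeline targets: a 19 HC / 67
#' no-disability / 33 disability cohort, 86 regions, 174 time points at
#' TR = 2.3 s, and 4 latent connectivity states.  Latent switching operates
#' at time-point resolution with high self-transition probability, so state
#' persistence (mean dwell 1/(1 - p_self) = 33 TR at the default 0.97) well
#' exceeds the 22-TR window length and window-level states are well defined.
#' The disability group dwells longer in state 1 (self-transition
#' `dwell_self_prob_dis`), and its within-state correlation strength in
#' `dfc_effect_networks` of state `dfc_effect_state` is scaled by
#' `dfc_regional_effect`.  SC node strength in `sc_effect_networks` is scaled
#' by `sc_strength_effect` for MS subjects.
#'
#' @param n_hc,n_ms_nodis,n_ms_dis group sizes.
#' @param R number of regions (>= 9; 86 uses the packaged atlas, other sizes
#'   get a proportional synthetic network assignment).
#' @param T_len time points per scan.
#' @param tr_seconds repetition time (s).
#' @param K_true number of latent covariance states.
#' @param self_prob baseline Markov self-transition probability per TR.
#' @param dwell_state state with the planted dwell-time group effect.
#' @param dwell_self_prob_dis self-transition probability of `dwell_state`
#'   in the disability group.
#' @param dwell_entry_boost relative weight (>= 1) with which the disability
#'   group's transitions out of other states favor `dwell_state`; the
#'   planted effect therefore combines longer stays with readier entry,
#'   which keeps the per-subject dwell distribution away from zero.
#' @param within_loading factor loading of regions in a network active in a
#'   state (drives within-block correlation).
#' @param cross_loading loading of the global between-network factor
#'   (alternating sign across networks per state, giving state-specific
#'   positive and negative between-block correlations).
#' @param base_sd region-specific baseline noise SD inside the state
#'   covariance.
#' @param observation_noise_sd isotropic observation noise SD added on top
#'   of the state covariance.
#' @param sc_base_density edge density of the shared SC sparsity mask.
#' @param sc_strength_effect multiplicative MS effect (> 0) on SC edges with
#'   an endpoint in `sc_effect_networks`.
#' @param sc_effect_networks networks carrying the SC group effect.
#' @param dfc_regional_effect multiplicative disability-group effect (> 0)
#'   on the within-state loadings of `dfc_effect_networks` in state
#'   `dfc_effect_state`.
#' @param dfc_effect_networks,dfc_effect_state target of the dFC effect.
#' @param seed master seed; every stage derives a child seed from it.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_hc = 19L, n_ms_nodis = 67L, n_ms_dis = 33L,
                         R = 86L, T_len = 174L, tr_seconds = 2.3,
                         K_true = 4L, self_prob = 0.992,
                         dwell_state = 1L, dwell_self_prob_dis = 0.999,
                         dwell_entry_boost = 4,
                         within_loading = 2.0, cross_loading = 0.5,
                         base_sd = 0.3, observation_noise_sd = 0.3,
                         sc_base_density = 0.4, sc_strength_effect = 0.8,
                         sc_effect_networks = c("DAN", "SUB", "CER"),
                         dfc_regional_effect = 1.15,
                         dfc_effect_networks = c("DAN", "VIS"),
                         dfc_effect_state = 2L, seed = 1L) {
  stopifnot(R >= 9, T_len >= 22, K_true >= 2,
            self_prob > 0, self_prob < 1,
            dwell_self_prob_dis > 0, dwell_self_prob_dis < 1,
            sc_strength_effect > 0, dfc_regional_effect > 0,
            dwell_state >= 1, dwell_state <= K_true,
            dfc_effect_state >= 1, dfc_effect_state <= K_true)
  structure(as.list(environment()), class = "synth_config")
}

# Proportional contiguous network assignment for non-86 region counts.
.synth_atlas <- function(R) {
  if (R == 86L) return(default_atlas())
  nets <- c("VIS", "SOM", "DAN", "VAN", "LIM", "FP", "DMN", "SUB", "CER")
  base <- c(VIS = 10, SOM = 10, DAN = 6, VAN = 8, LIM = 10, FP = 8,
            DMN = 16, SUB = 16, CER = 2)
  sizes <- pmax(1L, round(base / sum(base) * R))
  while (sum(sizes) > R) sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1L
  while (sum(sizes) < R) sizes[which.min(sizes)] <- sizes[which.min(sizes)] + 1L
  df <- data.frame(region_name = sprintf("region_%02d", seq_len(R)),
                   network = factor(rep(nets, sizes), levels = nets))
  class(df) <- c("atlas_networks", "data.frame")
  df
}

#' Atlas used by a synthetic configuration
#' @param cfg a [synth_config()].
#' @return an `atlas_networks` data.frame with `cfg$R` regions.
#' @export
synth_atlas <- function(cfg) .synth_atlas(cfg$R)

# Network-block state covariances as factor models: Sigma_k = D + L L^T,
# guaranteed SPD.  State k activates a balanced cyclic window of roughly
# half the networks (shifted per state, so every state activates the same
# number of networks and pairwise activation overlaps are comparable), and
# a global factor with a distinct balanced sign pattern per state adds
# state-specific between-network positive and negative correlations.
.build_state_covariances <- function(cfg, atlas, disability = FALSE) {
  nets <- atlas_network_levels(atlas)
  B <- length(nets)
  net_idx <- as.integer(atlas$network)
  R <- cfg$R
  K <- cfg$K_true
  n_active <- max(1L, round(B * 5 / 9))
  shift <- max(1L, B %/% K)
  covs <- vector("list", K)
  for (k in seq_len(K)) {
    Lmat <- matrix(0, R, B + 1L)
    for (b in seq_len(B)) {
      active <- ((b - 1L + shift * (k - 1L)) %% B) < n_active
      if (active) {
        load <- cfg$within_loading
        if (disability && k == cfg$dfc_effect_state &&
            nets[b] %in% cfg$dfc_effect_networks)
          load <- load * cfg$dfc_regional_effect
        Lmat[net_idx == b, b] <- load
      }
    }
    sgn <- ifelse(((seq_len(B) + k) %% K) < K / 2, 1, -1)
    Lmat[, B + 1L] <- cfg$cross_loading * sgn[net_idx]
    Sig <- tcrossprod(Lmat)
    diag(Sig) <- diag(Sig) + cfg$base_sd^2
    ev <- min(eigen(Sig, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0)
      stop("state covariance not SPD after perturbation; use a smaller effect size")
    covs[[k]] <- Sig
  }
  covs
}

#' Group transition matrices of a synthetic configuration
#' @param cfg a [synth_config()].
#' @return list with `HC`, `MS_NODIS`, `MS_DIS` row-stochastic K x K
#'   matrices.
#' @export
synth_transition_matrices <- function(cfg) {
  K <- cfg$K_true
  base <- matrix((1 - cfg$self_prob) / (K - 1), K, K)
  diag(base) <- cfg$self_prob
  dis <- base
  ds <- cfg$dwell_state
  dis[ds, ] <- (1 - cfg$dwell_self_prob_dis) / (K - 1)
  dis[ds, ds] <- cfg$dwell_self_prob_dis
  # readier entry into the dwell state from the other states
  for (i in seq_len(K)[-ds]) {
    leave <- 1 - cfg$self_prob
    wts <- rep(1, K); wts[ds] <- cfg$dwell_entry_boost; wts[i] <- 0
    dis[i, ] <- leave * wts / sum(wts)
    dis[i, i] <- cfg$self_prob
  }
  list(HC = base, MS_NODIS = base, MS_DIS = dis)
}

#' Sample a Markov state path
#'
#' @param P row-stochastic transition matrix.
#' @param n path length.
#' @param init initial distribution (default uniform).
#' @return integer state path of length `n` (uses the ambient RNG state).
#' @export
markov_path <- function(P, n, init = NULL) {
  K <- nrow(P)
  stopifnot(ncol(P) == K, all(abs(rowSums(P) - 1) < 1e-8))
  if (is.null(init)) init <- rep(1 / K, K)
  s <- integer(n)
  s[1L] <- sample.int(K, 1L, prob = init)
  for (t in seq_len(n - 1L))
    s[t + 1L] <- sample.int(K, 1L, prob = P[s[t], ])
  s
}

#' Generate a synthetic cohort
#'
#' Per subject: a latent state path is sampled from the subject's group
#' Markov chain at time-point resolution; observations are zero-mean
#' multivariate normal with the current state's covariance plus isotropic
#' observation noise.  SC matrices are symmetric nonnegative truncated-normal
#' weights on a sparsity mask shared across subjects, with the MS effect
#' applied to designated networks.  Demographics emulate an MS cohort
#' (older disability group, CIS phenotypes confined to the no-disability
#' group, EDSS consistent with the disability split at threshold 2).
#'
#' @param cfg a [synth_config()].
#' @return list of class `synth_cohort`: `subjects` (data.frame),
#'   `timeseries` (named list of [regional_timeseries()]), `sc` (named list
#'   of [conn_matrix()]), `atlas`, and `truth` (state paths, transition
#'   matrices, covariances, config).
#' @export
generate_cohort <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  atlas <- .synth_atlas(cfg$R)
  trans <- synth_transition_matrices(cfg)
  covs <- list(HC = .build_state_covariances(cfg, atlas, disability = FALSE),
               MS_DIS = .build_state_covariances(cfg, atlas, disability = TRUE))
  chol_hc <- lapply(covs$HC, function(S)
    chol(S + cfg$observation_noise_sd^2 * diag(cfg$R)))
  chol_dis <- lapply(covs$MS_DIS, function(S)
    chol(S + cfg$observation_noise_sd^2 * diag(cfg$R)))

  n <- cfg$n_hc + cfg$n_ms_nodis + cfg$n_ms_dis
  grp <- c(rep("HC", cfg$n_hc), rep("MS_NODIS", cfg$n_ms_nodis),
           rep("MS_DIS", cfg$n_ms_dis))
  ids <- sprintf("sub%03d", seq_len(n))

  set.seed(child_seed(cfg$seed, 1L))
  subjects <- data.frame(
    subject_id = ids,
    group = ifelse(grp == "HC", "HC", "MS"),
    age = round(rnorm(n, mean = c(HC = 44, MS_NODIS = 42, MS_DIS = 52)[grp],
                      sd = 9), 1),
    sex = ifelse(runif(n) < c(HC = 0.55, MS_NODIS = 0.69, MS_DIS = 0.61)[grp],
                 "F", "M"),
    race = sample(c("white", "black", "asian"), n, replace = TRUE,
                  prob = c(0.7, 0.2, 0.1)),
    disease_duration = ifelse(grp == "HC", NA,
                              round(rlnorm(n, meanlog = log(c(HC = 1, MS_NODIS = 10,
                                                              MS_DIS = 13)[grp]),
                                           sdlog = 0.5), 1)),
    phenotype = ifelse(grp == "HC", NA_character_,
                       ifelse(grp == "MS_NODIS",
                              sample(c("CIS", "RRMS"), n, replace = TRUE,
                                     prob = c(7, 60) / 67),
                              sample(c("RRMS", "PROG"), n, replace = TRUE,
                                     prob = c(28, 5) / 33))),
    spinal_lesion_cat = ifelse(grp == "HC", NA,
                               sample(0:2, n, replace = TRUE,
                                      prob = c(0.4, 0.3, 0.3))),
    edss = ifelse(grp == "HC", NA,
                  ifelse(grp == "MS_NODIS",
                         sample(seq(0, 1.5, 0.5), n, replace = TRUE),
                         sample(seq(2, 6, 0.5), n, replace = TRUE))),
    stringsAsFactors = FALSE)
  subjects <- validate_subjects(subjects)

  # shared SC sparsity mask (deterministic across subjects given the seed)
  set.seed(child_seed(cfg$seed, 2L))
  R <- cfg$R
  mask <- matrix(0L, R, R)
  ut <- upper.tri(mask)
  mask[ut] <- rbinom(sum(ut), 1L, cfg$sc_base_density)
  mask <- mask + t(mask)
  in_effect_net <- atlas$network %in% cfg$sc_effect_networks
  edge_mult <- outer(in_effect_net, in_effect_net, `|`)

  timeseries <- vector("list", n); names(timeseries) <- ids
  sc <- vector("list", n); names(sc) <- ids
  paths <- vector("list", n); names(paths) <- ids
  for (i in seq_len(n)) {
    set.seed(child_seed(cfg$seed, 10L + i))
    P <- trans[[grp[i]]]
    chols <- if (grp[i] == "MS_DIS") chol_dis else chol_hc
    path <- markov_path(P, cfg$T_len)
    Z <- matrix(rnorm(cfg$T_len * R), cfg$T_len, R)
    X <- matrix(0, cfg$T_len, R)
    for (k in unique(path)) {
      rows <- path == k
      X[rows, ] <- Z[rows, , drop = FALSE] %*% chols[[k]]
    }
    colnames(X) <- atlas$region_name
    timeseries[[i]] <- regional_timeseries(X, tr_seconds = cfg$tr_seconds,
                                           subject_id = ids[i])
    W <- matrix(0, R, R)
    W[ut] <- abs(rnorm(sum(ut), mean = 0.5, sd = 0.15))
    W <- (W + t(W)) * mask
    if (grp[i] != "HC")
      W[edge_mult] <- W[edge_mult] * cfg$sc_strength_effect
    dimnames(W) <- list(atlas$region_name, atlas$region_name)
    sc[[i]] <- conn_matrix(W, kind = "SC", region_names = atlas$region_name)
    paths[[i]] <- path
  }
  structure(list(subjects = subjects, timeseries = timeseries, sc = sc,
                 atlas = atlas,
                 truth = list(state_paths = paths, transition = trans,
                              covariances = covs, config = cfg)),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("synth_cohort: %d subjects (%d HC), R = %d, T = %d, K_true = %d\n",
              nrow(x$subjects), sum(x$subjects$group == "HC"),
              x$truth$config$R, x$truth$config$T_len, x$truth$config$K_true))
  invisible(x)
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' @param cohort a `synth_cohort`.
#' @param dir output directory (created if needed): `subjects.csv`,
#'   `atlas.csv`, `ts_<id>.tsv`, `sc_<id>.tsv`, and `truth.json` (state
#'   paths and scalar parameters).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synth_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_subjects(cohort$subjects, file.path(dir, "subjects.csv"))
  data.table::fwrite(as.data.frame(cohort$atlas), file.path(dir, "atlas.csv"))
  for (id in names(cohort$timeseries)) {
    write_timeseries(cohort$timeseries[[id]], file.path(dir, paste0("ts_", id, ".tsv")))
    write_conn_matrix(cohort$sc[[id]], file.path(dir, paste0("sc_", id, ".tsv")))
  }
  cfg <- cohort$truth$config
  jsonlite::write_json(
    list(state_paths = cohort$truth$state_paths,
         config = cfg[!vapply(cfg, is.list, TRUE)]),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Ground-truth state labels at window centers
#'
#' The time-point-resolution truth path is resampled at the center of each
#' sliding window, giving a window-level truth labeling comparable with
#' clustering assignments.
#'
#' @param path integer state path at TR resolution.
#' @param spec a [window_spec()].
#' @return integer vector over windows.
#' @export
truth_window_states <- function(path, spec) {
  Tn <- length(path)
  L <- spec$length_tr; st <- spec$step_tr
  W <- (Tn - L) %/% st + 1L
  centers <- (seq_len(W) - 1L) * st + 1L + (L - 1L) %/% 2L
  path[centers]
}

#' Match recovered cluster labels to ground-truth states
#'
#' Greedy maximum-overlap matching of the contingency table between
#' window-center truth labels and cluster assignments: repeatedly take the
#' largest remaining cell.  With well-separated states this is the optimal
#' permutation.
#'
#' @param truth the `truth` element of a [generate_cohort()] result.
#' @param model a `state_model`.
#' @param spec the [window_spec()] used to build the windows.
#' @return integer vector `m` of length `model$K`: `m[c]` is the truth state
#'   matched to cluster label `c` (`NA` when K exceeds the truth state
#'   count).
#' @export
match_states <- function(truth, model, spec) {
  stopifnot(inherits(model, "state_model"))
  ids <- names(model$assignments)
  tw <- unlist(lapply(truth$state_paths[ids], truth_window_states, spec = spec))
  mw <- unlist(model$assignments)
  K_true <- max(tw)
  tab <- table(factor(mw, levels = seq_len(model$K)),
               factor(tw, levels = seq_len(K_true)))
  m <- rep(NA_integer_, model$K)
  tab <- as.matrix(tab)
  for (step in seq_len(min(model$K, K_true))) {
    cell <- which(tab == max(tab), arr.ind = TRUE)[1L, ]
    m[cell[1L]] <- cell[2L]
    tab[cell[1L], ] <- -1
    tab[, cell[2L]] <- -1
  }
  m
}

#' Adjusted Rand index between ground-truth and recovered states
#'
#' Truth paths are resampled at window centers and compared with the model's
#' window assignments; the index is invariant to label permutation and 1 for
#' identical partitions.
#'
#' @param truth the `truth` element of a [generate_cohort()] result (or a
#'   list with `state_paths`).
#' @param model a `state_model` from [cluster_states()].
#' @param spec the [window_spec()] used to build the windows.
#' @return adjusted Rand index in \[-1, 1\].
#' @export
truth_state_overlap <- function(truth, model, spec) {
  stopifnot(inherits(model, "state_model"))
  ids <- names(model$assignments)
  tw <- unlist(lapply(truth$state_paths[ids], truth_window_states, spec = spec))
  mw <- unlist(model$assignments)
  if (length(tw) != length(mw))
    stop("truth and model cover different numbers of windows")
  mclust::adjustedRandIndex(tw, mw)
}
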