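test_that("taper weights are a normalized, symmetric, center-peaked kernel", {
  # sigma -> 0 reduces to the uniform rectangle
  w0 <- build_taper(window_spec(gauss_sigma_tr = 0))
  expect_equal(w0, rep(1 / 22, 22))

  w <- build_taper(window_spec())
  expect_equal(length(w), 22L)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(w > 0))
  expect_equal(w, rev(w), tolerance = 1e-12)
  # non-increasing from center to the edges
  expect_true(all(diff(w[1:11]) >= -1e-12))
  expect_true(all(diff(w[12:22]) <= 1e-12))

  # normalization holds for arbitrary specs
  for (L in c(5, 22, 40)) for (s in c(0.5, 3, 7))
    expect_equal(sum(build_taper(window_spec(length_tr = L, gauss_sigma_tr = s))),
                 1, tolerance = 1e-12)
})

test_that("window count follows floor((T - length)/step) + 1", {
  ts <- make_ts(T_len = 174, R = 3, seed = 1)
  expect_equal(windowed_dfc(ts, window_spec())$n_windows, 153L)
  for (case in list(c(50, 10, 3), c(22, 22, 1), c(100, 22, 5))) {
    ts2 <- make_ts(T_len = case[1], R = 3, seed = 2)
    sp <- window_spec(length_tr = case[2], step_tr = case[3])
    expect_equal(windowed_dfc(ts2, sp)$n_windows,
                 (case[1] - case[2]) %/% case[3] + 1)
  }
  expect_error(windowed_dfc(make_ts(T_len = 10, R = 3), window_spec()),
               "shorter than window")
})

test_that("uniform taper reduces windowed dFC to plain Pearson on each slice", {
  ts <- make_ts(T_len = 40, R = 4, seed = 11)
  sp <- window_spec(length_tr = 10, step_tr = 5, gauss_sigma_tr = 0)
  dw <- windowed_dfc(ts, sp)
  for (w in seq_len(dw$n_windows)) {
    sl <- ts$data[((w - 1) * 5 + 1):((w - 1) * 5 + 10), ]
    plain <- cor(sl); diag(plain) <- 0
    expect_equal(dfc_window_matrix(dw, w)$data, plain, tolerance = 1e-12)
  }
})

test_that("tapered windowed correlation matches a brute-force weighted oracle", {
  ts <- make_ts(T_len = 30, R = 4, seed = 13)
  sp <- window_spec(length_tr = 22, step_tr = 1, gauss_sigma_tr = 3)
  dw <- windowed_dfc(ts, sp)
  w <- build_taper(sp)
  for (win in seq_len(dw$n_windows)) {
    sl <- ts$data[win:(win + 21), ]
    m <- dfc_window_matrix(dw, win)$data
    for (i in 1:3) for (j in (i + 1):4)
      expect_equal(m[i, j], wpearson_bf(sl[, i], sl[, j], w),
                   tolerance = 1e-12)
  }
})

test_that("L1 k-means separates well-separated clouds exactly", {
  set.seed(5)
  centers <- matrix(c(0, 0, 20, 0, 0, 20, 20, 20), 4, 2, byrow = TRUE)
  truth <- rep(1:4, each = 30)
  X <- centers[truth, ] + matrix(rnorm(240, sd = 0.5), 120, 2)
  wl <- list(s1 = X[1:60, ], s2 = X[61:120, ])
  m <- cluster_states(wl, K = 4, seed = 3)
  got <- unlist(m$assignments)
  expect_equal(mclust::adjustedRandIndex(got, truth), 1)

  # K = n gives zero inertia, each point its own centroid
  small <- list(s = matrix(rnorm(12), 6, 2))
  m2 <- cluster_states(small, K = 6, seed = 1)
  expect_equal(m2$inertia, 0)

  # duplicating every point leaves the solution unchanged
  m3 <- cluster_states(list(s1 = X, s2 = X), K = 4, seed = 3)
  c_sorted <- function(cm) cm[do.call(order, as.data.frame(cm)), ]
  expect_equal(c_sorted(m3$centroids), c_sorted(m$centroids), tolerance = 1e-12)
})

test_that("states are relabeled by descending occupancy", {
  set.seed(8)
  X <- rbind(matrix(rnorm(20, mean = 0, sd = .1), 10, 2),
             matrix(rnorm(80, mean = 10, sd = .1), 40, 2))
  m <- cluster_states(list(s = X), K = 2, seed = 2)
  expect_true(m$occupancy[1] >= m$occupancy[2])
  expect_equal(sort(m$occupancy), sort(c(10L, 40L)))
})

test_that("elbow pick maximizes curvature and breaks ties toward small K", {
  # strictly linear curve: all second differences 0, first interior wins
  expect_equal(dynconn:::.elbow_pick(c(5, 4, 3, 2, 1)), 2L)
  # clear kink at the third point
  expect_equal(dynconn:::.elbow_pick(c(5, 3, 1.2, 1.1, 1.0)), 3L)
  expect_error(dynconn:::.elbow_pick(c(1, 2)), "at least 3")
  expect_error(select_k_elbow(list(s = matrix(rnorm(40), 20, 2)),
                              k_range = 2:3),
               "at least 3")
})

test_that("state metrics match hand enumeration", {
  sm <- state_metrics(c(1, 1, 2, 2, 2, 1), K = 2)
  expect_equal(sm$mean_dwell, c(1.5, 3))
  expect_equal(sm$n_transitions, 2L)
  expect_equal(sm$transition_prob, matrix(c(.5, 1/3, .5, 2/3), 2, 2))

  sm2 <- state_metrics(c(3, 3, 3, 3), K = 4)
  expect_equal(sm2$mean_dwell, c(0, 0, 4, 0))
  expect_equal(sm2$n_transitions, 0L)
  expect_equal(sm2$transition_prob[3, ], c(0, 0, 1, 0))
  expect_equal(sm2$visited, c(FALSE, FALSE, TRUE, FALSE))

  sm3 <- state_metrics(c(1, 2, 1, 2, 1), K = 2)
  expect_equal(sm3$mean_dwell, c(1, 1))
  expect_equal(sm3$n_transitions, 4L)
  expect_equal(sm3$transition_prob, matrix(c(0, 1, 1, 0), 2, 2))

  expect_error(state_metrics(c(1, 5), K = 2), "1..K")
})

test_that("state metrics satisfy the bookkeeping identities on random sequences", {
  set.seed(31)
  for (rep in 1:20) {
    K <- sample(2:5, 1)
    s <- sample(seq_len(K), 60, replace = TRUE)
    sm <- state_metrics(s, K)
    runs <- rle(s)
    # total windows per state = number of runs x mean dwell
    for (k in seq_len(K)) {
      nk <- sum(runs$values == k)
      expect_equal(nk * sm$mean_dwell[k], sum(s == k))
    }
    # transitions equal off-diagonal transition counts
    expect_equal(sm$n_transitions, sum(runs$lengths > 0) - 1L)
    expect_true(sm$n_transitions <= length(s) - 1L)
    # visited rows are proper distributions
    expect_equal(unname(rowSums(sm$transition_prob)), rep(1, K))
    expect_true(all(sm$mean_dwell[sm$visited] >= 1))
  }
})

test_that("subject centroids are per-state window means with positive-part strengths", {
  # all windows identical: every visited centroid equals that window
  v <- vectorize_pairwise(make_sym(4, seed = 21))
  W <- rbind(v, v, v)
  sc <- subject_centroids(W, c(1, 2, 1), K = 2, R = 4)
  expect_equal(unname(vectorize_pairwise(sc$centroids[[1]])), unname(v),
               tolerance = 1e-12)
  expect_equal(unname(vectorize_pairwise(sc$centroids[[2]])), unname(v),
               tolerance = 1e-12)

  # mean of entries 0.2 and 0.4 is 0.3
  W2 <- rbind(rep(0.2, 6), rep(0.4, 6))
  sc2 <- subject_centroids(W2, c(1, 1), K = 2, R = 4)
  expect_equal(unname(vectorize_pairwise(sc2$centroids[[1]])), rep(0.3, 6))
  expect_true(is.null(sc2$centroids[[2]]))
  expect_true(all(is.na(sc2$regional_dfc[2, ])))

  # mixed-sign centroid: regional dFC equals hand-computed positive-part sums
  m <- conn_matrix(matrix(c(0, .5, -.2, .5, 0, .3, -.2, .3, 0), 3), "DFC_CENTROID")
  sc3 <- subject_centroids(rbind(vectorize_pairwise(m)), 1L, K = 1, R = 3)
  expect_equal(unname(sc3$regional_dfc[1, ]), c(0.5, 0.8, 0.3))
  expect_true(all(sc3$regional_dfc >= 0, na.rm = TRUE))
})
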