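test_that("compute_fc matches the textbook Pearson formula", {
  # hand case x = (1,2,3,4), y = (1,2,2,5) against the brute-force oracle
  x <- c(1, 2, 3, 4); y <- c(1, 2, 2, 5)
  ts <- regional_timeseries(cbind(a = x, b = y, c = rnorm(4)), 2.3)
  fc <- compute_fc(ts)
  expect_equal(fc$data["a", "b"], pearson_bf(x, y), tolerance = 1e-12)

  # random matrix, all entries vs oracle
  ts2 <- make_ts(T_len = 30, R = 4, seed = 3)
  fc2 <- compute_fc(ts2)
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(fc2$data[i, j], pearson_bf(ts2$data[, i], ts2$data[, j]),
                 tolerance = 1e-12)
})

test_that("compute_fc hits the correlation extremes and rejects flat regions", {
  x <- rnorm(20)
  ts <- regional_timeseries(cbind(a = x, b = x, c = -x), 2.3)
  fc <- compute_fc(ts)
  expect_equal(fc$data["a", "b"], 1)
  expect_equal(fc$data["a", "c"], -1)
  expect_equal(diag(fc$data), rep(0, 3), ignore_attr = TRUE)

  flat <- regional_timeseries(cbind(a = x, b = rep(1, 20)), 2.3)
  expect_error(compute_fc(flat), "zero-variance.*b")
})

test_that("compute_fc is invariant to positive affine rescaling of a column", {
  ts <- make_ts(T_len = 25, R = 3, seed = 9)
  ts2 <- ts
  ts2$data[, 2] <- 3.7 * ts2$data[, 2] + 11
  expect_equal(compute_fc(ts)$data, compute_fc(ts2)$data, tolerance = 1e-12)
})

test_that("node strength follows the positive-part column-sum convention", {
  m <- conn_matrix(matrix(c(0, .5, -.2, .5, 0, .3, -.2, .3, 0), 3), kind = "FC")
  expect_equal(unname(node_strength(m, drop_negatives = TRUE)),
               c(0.5, 0.8, 0.3))
  expect_equal(unname(node_strength(m, drop_negatives = FALSE)),
               c(0.3, 0.8, 0.1))
  expect_equal(node_strength(conn_matrix(matrix(0, 4, 4), "FC"), TRUE),
               rep(0, 4))
  # on a nonnegative matrix the flag makes no difference
  sc <- make_sym(5, seed = 2)
  sc$data <- abs(sc$data)
  expect_equal(node_strength(sc, TRUE), node_strength(sc, FALSE))
  # dropping negatives can only increase strength
  fc <- make_sym(6, seed = 4)
  expect_true(all(node_strength(fc, TRUE) >= node_strength(fc, FALSE)))
})

test_that("pairwise vectorization is row-major upper triangle with exact counts", {
  m <- make_sym(3, seed = 5)
  v <- vectorize_pairwise(m)
  expect_equal(length(v), 3L)
  expect_equal(names(v), c("r1|r2", "r1|r3", "r2|r3"))
  expect_equal(unname(v), c(m$data[1, 2], m$data[1, 3], m$data[2, 3]))

  m86 <- conn_matrix(matrix(0, 86, 86), kind = "FC")
  expect_equal(length(vectorize_pairwise(m86)), 3655L)

  # round trip through devectorize
  m5 <- make_sym(5, seed = 6)
  back <- devectorize_pairwise(vectorize_pairwise(m5), 5,
                               region_names = rownames(m5$data))
  expect_equal(back$data, m5$data, tolerance = 1e-15)
})

test_that("SC prevalence filter uses a strict majority of controls", {
  mk <- function(val) conn_matrix(matrix(c(0, val, val, 0), 2), kind = "SC")
  # 10 of 19 controls nonzero -> kept; 9 of 19 -> dropped
  keep10 <- c(replicate(10, mk(1), simplify = FALSE),
              replicate(9, mk(0), simplify = FALSE))
  expect_true(sc_prevalence_filter(keep10)[1, 2])
  keep9 <- c(replicate(9, mk(1), simplify = FALSE),
             replicate(10, mk(0), simplify = FALSE))
  expect_false(sc_prevalence_filter(keep9)[1, 2])
  # nonzero in all controls -> kept
  expect_true(sc_prevalence_filter(replicate(5, mk(2), simplify = FALSE))[1, 2])
  # exactly half (2 of 4) -> dropped (strict inequality)
  half <- c(replicate(2, mk(1), simplify = FALSE),
            replicate(2, mk(0), simplify = FALSE))
  expect_false(sc_prevalence_filter(half)[1, 2])
  expect_error(sc_prevalence_filter(list()), "at least one")
})

test_that("feature tables have the closed-form connectome column counts", {
  atlas <- synth_atlas(synth_config(R = 10))
  R <- 10; K <- 3
  subj <- data.frame(subject_id = c("s1", "s2", "s3"),
                     group = c("HC", "MS", "MS"), age = c(40, 50, 60),
                     sex = c("F", "M", "F"), race = "white",
                     edss = c(NA, 1, 3))
  subj <- validate_subjects(subj)
  mats <- lapply(1:3, function(i) make_sym(R, seed = i))
  names(mats) <- subj$subject_id

  ft <- build_feature_table(subj, mats, "PAIR_FC", atlas)
  expect_equal(length(ft$connectome_cols), R * (R - 1) / 2)

  cents <- lapply(1:3, function(i)
    lapply(1:K, function(k) make_sym(R, seed = 10 * i + k)))
  names(cents) <- subj$subject_id
  ft2 <- build_feature_table(subj, cents, "PAIR_DFC", atlas, K = K)
  expect_equal(length(ft2$connectome_cols), K * R * (R - 1) / 2)

  regs <- lapply(1:3, function(i) matrix(abs(rnorm(K * R)), K, R))
  names(regs) <- subj$subject_id
  ft3 <- build_feature_table(subj, regs, "REG_DFC", atlas, K = K)
  expect_equal(length(ft3$connectome_cols), K * R)

  mets <- lapply(1:3, function(i) state_metrics(sample(1:K, 30, TRUE), K))
  names(mets) <- subj$subject_id
  ft4 <- build_feature_table(subj, mets, "DFC_METRICS", atlas, K = K)
  expect_equal(length(ft4$connectome_cols), K + K^2 + 1)

  # covariate block: one-hot with reference level dropped, no duplicates
  expect_true(all(c("age", "sex_M") %in% ft$covariate_cols))
  expect_equal(anyDuplicated(ft$feature_names), 0L)
})

test_that("disability-task tables add clinical covariates", {
  atlas <- synth_atlas(synth_config(R = 10))
  subj <- validate_subjects(data.frame(
    subject_id = c("s1", "s2", "s3", "s4"), group = "MS",
    age = c(40, 50, 60, 45), sex = c("F", "M", "F", "M"), race = "white",
    disease_duration = c(5, 10, 15, 8), phenotype = c("CIS", "RRMS", "PROG", "RRMS"),
    spinal_lesion_cat = c(0, 1, 2, 1), edss = c(1, 1.5, 3, 2)))
  mats <- lapply(1:4, function(i) make_sym(10, seed = i))
  names(mats) <- subj$subject_id
  ft <- build_feature_table(subj, mats, "REG_FC", atlas, task = "disability")
  expect_true("disease_duration" %in% ft$covariate_cols)
  expect_true(any(grepl("^phenotype_", ft$covariate_cols)))
  expect_true(any(grepl("^spinal_lesion_cat_", ft$covariate_cols)))
})
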