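# Shared fixture builders.  Everything is generated in code at test time.

# Small random time series with named regions.
make_ts <- function(T_len = 40, R = 4, seed = 1, tr = 2.3) {
  set.seed(seed)
  X <- matrix(rnorm(T_len * R), T_len, R,
              dimnames = list(NULL, paste0("r", seq_len(R))))
  regional_timeseries(X, tr_seconds = tr, subject_id = paste0("s", seed))
}

# Random symmetric matrix with zero diagonal, entries in [-1, 1].
make_sym <- function(R = 5, seed = 1, kind = "FC") {
  set.seed(seed)
  m <- matrix(runif(R * R, -1, 1), R, R)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  conn_matrix(m, kind = kind, region_names = paste0("r", seq_len(R)))
}

# Independent brute-force Pearson correlation (textbook formula).
pearson_bf <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Independent brute-force weighted Pearson correlation under weights w
# (sum(w) need not be 1).
wpearson_bf <- function(x, y, w) {
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  cxy <- sum(w * (x - mx) * (y - my))
  cxx <- sum(w * (x - mx)^2); cyy <- sum(w * (y - my)^2)
  cxy / sqrt(cxx * cyy)
}

# Independent brute-force BH step-up adjustment.
bh_bf <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- Inf
  for (i in m:1) {
    val <- min(prev, m * p[ord[i]] / i)
    q[ord[i]] <- min(val, 1)
    prev <- val
  }
  q
}

# Independent brute-force AUC by pair counting (ties count one half).
auc_bf <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Independent fixed-step gradient-descent oracle for ridge logistic
# regression: mean NLL + lambda * ||w||^2, unpenalized intercept.
ridge_gd_oracle <- function(X, y, lambda, step = 0.1, iters = 200000) {
  n <- nrow(X); p <- ncol(X)
  w <- rep(0, p); b <- 0
  for (i in seq_len(iters)) {
    mu <- 1 / (1 + exp(-(drop(X %*% w) + b)))
    gw <- drop(crossprod(X, mu - y)) / n + 2 * lambda * w
    gb <- mean(mu - y)
    w <- w - step * gw
    b <- b - step * gb
    if (max(abs(c(gw, gb))) < 1e-10) break
  }
  list(w = w, b = b)
}
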