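# shared fixtures, all generated in code

# compact three-year breeding programme for fast end-to-end tests
small_sim <- function(seed = 42, n_lines = 240, ...) {
  cfg <- sim_config(
    n_lines = n_lines, n_families = 60, n_markers = 400,
    years = data.frame(year = 2010:2013, n_trials = 2L, n_reps = 2L,
                       role = c("training", "training", "training",
                                "validation")),
    seed = seed, ...)
  simulate_population(cfg)
}

# random coded marker matrix without missing values
random_markers <- function(n, m, seed = 1, maf = c(0.1, 0.5)) {
  with_seed <- function(s, code) { set.seed(s); code }
  with_seed(seed, {
    p <- runif(m, maf[1], maf[2])
    z <- matrix(2L * rbinom(n * m, 1L, rep(p, each = n)) - 1L, n, m)
    dimnames(z) <- list(sprintf("L%03d", seq_len(n)),
                        sprintf("M%03d", seq_len(m)))
    z
  })
}

# simulate y = g + e on a given kinship with known variances
simulate_gblup_y <- function(K, sigma2_G, sigma2_e, seed = 1) {
  set.seed(seed)
  n <- nrow(K)
  ev <- eigen(unclass(K), symmetric = TRUE)
  d <- pmax(ev$values, 0)
  g <- drop(ev$vectors %*% (sqrt(d * sigma2_G) * rnorm(n)))
  y <- g + rnorm(n, 0, sqrt(sigma2_e))
  names(y) <- rownames(K)
  list(y = y, g = setNames(g, rownames(K)))
}

# independent REML oracle for the GBLUP variance ratio: coarse-to-fine
# grid search on the -2 restricted log-likelihood over log(lambda)
grid_reml_lambda <- function(y, K) {
  n <- length(y)
  X <- matrix(1, n, 1)
  Ksub <- unclass(K)[names(y), names(y)]
  m2ll <- function(lam) {
    V <- Ksub + diag(lam, n)   # up to sigma2_G factor
    ch <- chol(V)
    Vi <- chol2inv(ch)
    B <- crossprod(X, Vi %*% X)
    bh <- solve(B, crossprod(X, Vi %*% y))
    r <- y - X %*% bh
    s2g <- drop(crossprod(r, Vi %*% r)) / (n - 1)
    (n - 1) * log(s2g) + 2 * sum(log(diag(ch))) + log(B[1, 1])
  }
  lo <- -12; hi <- 12
  for (pass in 1:4) {
    grid <- seq(lo, hi, length.out = 41)
    vals <- vapply(grid, function(l) m2ll(exp(l)), numeric(1))
    i <- which.min(vals)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  }
  exp((lo + hi) / 2)
}
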