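make_trial <- function(true, reps = 2, sd_e = 0, trial = "T1", trait = "GY",
                       seed = 1) {
  set.seed(seed)
  n <- length(true)
  ids <- sprintf("L%02d", seq_len(n))
  do.call(rbind, lapply(seq_len(reps), function(r)
    data.frame(line_id = ids, trial_id = trial, year = 2010, stage = "MET",
               trait = trait, replicate = r,
               value = true + rnorm(n, 0, sd_e), stringsAsFactors = FALSE)))
}

test_that("noiseless balanced trials give line means and unit repeatability", {
  true <- c(10, 12, 14, 16, 18)
  d <- make_trial(true, reps = 2, sd_e = 0)
  s <- trial_blues(d)
  expect_equal(unname(s$blues), true, tolerance = 1e-10)
  expect_equal(s$h2, 1)
  expect_equal(s$MVD, 0, tolerance = 1e-12)
})

test_that("no genetic signal drives repeatability towards zero", {
  d <- make_trial(rep(10, 40), reps = 2, sd_e = 1, seed = 4)
  s <- trial_blues(d)
  expect_lt(s$h2, 0.2)
})

test_that("trial REML matches an independent grid-search oracle", {
  # oracle: brute-force -2 restricted log-likelihood of the one-random-
  # factor model (line random, replicate fixed) evaluated on a refined
  # 2-D grid over the variance components, dense matrix algebra only
  set.seed(8)
  n <- 40; reps <- 2
  true <- rnorm(n, 0, 1)
  d <- make_trial(true, reps = reps, sd_e = 1, seed = 9)
  s <- trial_blues(d)

  Zl <- model.matrix(~ 0 + factor(d$line_id))
  X <- model.matrix(~ factor(d$replicate))
  ZZt <- tcrossprod(Zl)
  N <- nrow(X); p <- ncol(X)
  m2ll <- function(s2g, s2e) {
    V <- s2g * ZZt + diag(s2e, N)
    ch <- chol(V)
    Vi <- chol2inv(ch)
    B <- crossprod(X, Vi %*% X)
    bh <- solve(B, crossprod(X, Vi %*% d$value))
    r <- d$value - X %*% bh
    2 * sum(log(diag(ch))) + determinant(B)$modulus +
      drop(crossprod(r, Vi %*% r))
  }
  rg_g <- log(c(0.02, 10)); rg_e <- log(c(0.02, 10))
  for (pass in 1:4) {
    gg <- seq(rg_g[1], rg_g[2], length.out = 40)
    ge <- seq(rg_e[1], rg_e[2], length.out = 40)
    grid <- expand.grid(s2g = exp(gg), s2e = exp(ge))
    vals <- mapply(m2ll, grid$s2g, grid$s2e)
    best <- grid[which.min(vals), ]
    ig <- which.min(abs(gg - log(best$s2g)))
    ie <- which.min(abs(ge - log(best$s2e)))
    rg_g <- gg[c(max(1, ig - 1), min(40, ig + 1))]
    rg_e <- ge[c(max(1, ie - 1), min(40, ie + 1))]
  }
  expect_equal(s$sigma2_G / s$sigma2_e, best$s2g / best$s2e,
               tolerance = 1e-4)
  expect_equal(s$h2, best$s2g / (best$s2g + s$MVD / 2), tolerance = 0.01)
})

test_that("the repeatability identity holds on every summary", {
  sim <- small_sim(seed = 31, n_lines = 120)
  met <- sim$phenotypes[sim$phenotypes$stage == "MET", ]
  tr <- unique(met$trial_id)[1:3]
  for (t in tr) {
    s <- trial_blues(met[met$trial_id == t & met$trait == "GY", ])
    expect_equal(s$h2,
                 min(1, max(0, s$sigma2_G / (s$sigma2_G + s$MVD / 2))))
  }
})

test_that("unreplicated trials return check-adjusted values and flag h2", {
  cand <- data.frame(line_id = sprintf("C%02d", 1:8), trial_id = "P1",
                     year = 2011, stage = "PYT", trait = "GY",
                     replicate = 1, value = 10 + 1:8,
                     stringsAsFactors = FALSE)
  checks <- data.frame(line_id = rep(c("CHK1", "CHK2"), each = 3),
                       trial_id = "P1", year = 2011, stage = "PYT",
                       trait = "GY", replicate = rep(1:3, 2),
                       value = c(11, 12, 13, 14, 15, 16),
                       stringsAsFactors = FALSE)
  expect_warning(s <- trial_blues(rbind(cand, checks)),
                 "unestimable repeatability")
  expect_true(is.na(s$h2))
  chk_mean <- mean(checks$value)
  expect_equal(unname(s$blues[cand$line_id]), cand$value - chk_mean)
  # no checks at all: centered raw values
  expect_warning(s2 <- trial_blues(cand), "unestimable")
  expect_equal(unname(s2$blues[cand$line_id]), cand$value - mean(cand$value))
})

test_that("the trial filter keeps strictly-above-threshold and unestimable trials", {
  mk <- function(h2) structure(list(trial_id = "t", trait = "GY", h2 = h2),
                               class = "trial_summary")
  s <- lapply(c(0.1, 0.3, 0.31), mk)
  kept <- filter_trials(s)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$h2, 0.31)
  expect_length(filter_trials(list()), 0)
  expect_length(filter_trials(lapply(c(1, 1, 1), mk)), 3)
  expect_length(filter_trials(list(mk(NA_real_))), 1)
  expect_length(filter_trials(list(mk(NA_real_)), keep_unestimable = FALSE), 0)
})

test_that("across-trial combination matches the balanced two-way solution", {
  set.seed(5)
  n <- 12; tr <- 3
  true <- rnorm(n, 20, 2)
  teff <- c(0, 3, -2)
  d <- expand.grid(line_id = sprintf("L%02d", 1:n), trial_id = paste0("T", 1:tr),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$value <- true[match(d$line_id, sprintf("L%02d", 1:n))] +
    teff[match(d$trial_id, paste0("T", 1:tr))]
  cb <- combine_trials(d)
  # balanced complete data: BLUE_i equals the line mean across trials
  oracle <- tapply(d$value, d$line_id, mean)
  expect_equal(unname(cb$blues), as.vector(oracle[names(cb$blues)]),
               tolerance = 1e-10)
  # per-trial translation invariance: line contrasts are unchanged when a
  # constant is added to every record of one trial (BLUEs shift uniformly)
  d2 <- d
  d2$value[d2$trial_id == "T2"] <- d2$value[d2$trial_id == "T2"] + 100
  cb2 <- combine_trials(d2)
  expect_equal(cb2$blues - mean(cb2$blues), cb$blues - mean(cb$blues),
               tolerance = 1e-9)
})

test_that("single-trial combination is a passthrough", {
  d <- data.frame(line_id = c("A", "B", "C"), trial_id = "T1",
                  value = c(1, 2, 3), stringsAsFactors = FALSE)
  cb <- combine_trials(d)
  expect_equal(unname(cb$blues), c(1, 2, 3))
  expect_true(is.na(cb$sigma2_G))
})

test_that("disconnected designs are reported with their trial groups", {
  d <- data.frame(line_id = c("A", "B", "C", "D"),
                  trial_id = c("T1", "T1", "T2", "T2"),
                  value = 1:4, stringsAsFactors = FALSE)
  expect_error(combine_trials(d), "disconnected.*T1.*T2")
})
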