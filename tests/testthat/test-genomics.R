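test_that("marker QC applies the three thresholds with the right strictness", {
  set.seed(1)
  n <- 40
  mk <- random_markers(n, 4, seed = 2)
  colnames(mk) <- c("ok", "miss15", "maf_low", "maf_edge")
  mk <- matrix(as.integer(mk), n, 4, dimnames = dimnames(mk))
  mk[, "ok"] <- rep(c(-1L, 1L), n / 2)                 # MAF 0.5, complete
  mk[1:6, "miss15"] <- NA                              # 15% missing
  mk[, "maf_low"] <- c(1L, rep(-1L, n - 1))            # MAF 0.0125
  mk[, "maf_edge"] <- c(rep(1L, n * 0.05), rep(-1L, n * 0.95))  # MAF 0.05
  out <- qc_markers(mk)
  expect_setequal(colnames(out), c("ok", "maf_edge"))
  rep <- attr(out, "qc_report")
  expect_equal(unname(rep["removed"]), 2)
  expect_gte(rep[["too_missing"]], 1)
  expect_error(qc_markers(mk[, "maf_low", drop = FALSE]), "all markers removed")
})

test_that("mean imputation fills missing codes and leaves complete data alone", {
  mk <- matrix(c(1L, 1L, -1L, NA,
                 1L, -1L, 1L, -1L,
                 0L, 0L, NA, 0L), 4, 3,
               dimnames = list(paste0("L", 1:4), paste0("M", 1:3)))
  imp <- impute_markers(mk)
  expect_equal(imp[4, 1], 1 / 3)
  expect_equal(imp[3, 3], 0)
  expect_false(anyNA(imp))
  complete <- mk[, 2, drop = FALSE]
  expect_equal(impute_markers(complete), {
    x <- complete; storage.mode(x) <- "double"; x
  })
  allna <- mk; allna[, 2] <- NA
  expect_error(impute_markers(allna), "zero observed calls")
})

test_that("kinship matches a scalar-loop evaluation of the relationship formula", {
  mk <- matrix(c(-1L, 1L, 1L,
                 1L, -1L, 1L,
                 -1L, -1L, 1L,
                 0L, 1L, -1L), 3, 4,
               dimnames = list(c("A", "B", "C"), paste0("M", 1:4)))
  K <- compute_kinship(impute_markers(mk))
  # independent scalar-loop oracle
  p <- numeric(4); W <- matrix(0, 3, 4)
  for (k in 1:4) p[k] <- mean((mk[, k] + 1) / 2)
  for (i in 1:3) for (k in 1:4) W[i, k] <- mk[i, k] + 1 - 2 * p[k]
  denom <- 0
  for (k in 1:4) denom <- denom + 2 * p[k] * (1 - p[k])
  Ko <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3)
    Ko[i, j] <- sum(W[i, ] * W[j, ]) / denom
  expect_equal(unclass(K), Ko, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(attr(K, "scaling"), denom)
})

test_that("kinship rows sum to zero and duplicate lines coincide", {
  mk <- random_markers(30, 80, seed = 5)
  mk[2, ] <- mk[1, ]  # duplicate line
  K <- compute_kinship(impute_markers(mk))
  expect_lt(max(abs(rowSums(K))), 1e-10 * max(abs(K)))
  expect_equal(K[1, 1], K[1, 2], tolerance = 1e-12)
  expect_equal(K[1, 1], K[2, 2], tolerance = 1e-12)
  mono <- matrix(1L, 5, 3, dimnames = list(paste0("L", 1:5), paste0("M", 1:3)))
  expect_error(compute_kinship(mono), "polymorphic")
})

test_that("GBLUP with identity kinship shrinks by the variance ratio", {
  set.seed(11)
  n <- 50
  ids <- sprintf("L%02d", 1:n)
  K <- diag(n); dimnames(K) <- list(ids, ids)
  y <- setNames(rnorm(n, 10, 2), ids)
  fit <- fit_gblup(y, K)
  lam <- fit$sigma2_e / fit$sigma2_G
  # closed form: g = (I + lambda I)^{-1} centered GLS residual
  mu_gls <- mean(y)  # X = 1, V proportional to I
  oracle <- (y - mu_gls) / (1 + lam)
  expect_equal(unname(fit$g), unname(oracle - mean(oracle)), tolerance = 1e-8)
  expect_lt(abs(mean(fit$g)), 1e-6 * sd(fit$g))
})

test_that("GBLUP equals ridge-regression BLUP on the marker scale", {
  # oracle: dense mixed-model-equation solve of the marker model
  for (seed in c(3, 17)) {
    set.seed(seed)
    n <- 150; m <- 400
    mk <- random_markers(n, m, seed = seed + 1)
    K <- compute_kinship(impute_markers(mk))
    c0 <- attr(K, "scaling")
    g <- drop(mk %*% rnorm(m, 0, 0.15))
    y <- setNames(g + rnorm(n, 0, 1.5), rownames(mk))
    fit <- fit_gblup(y, K)

    p <- colMeans((mk + 1) / 2)
    W <- sweep(mk + 1, 2, 2 * p, `-`)
    lam_m <- c0 * fit$sigma2_e / fit$sigma2_G
    A <- rbind(cbind(n, t(rep(1, n)) %*% W),
               cbind(crossprod(W, rep(1, n)), crossprod(W) + diag(lam_m, m)))
    rhs <- c(sum(y), crossprod(W, y))
    sol <- solve(A, rhs)
    gebv_rr <- sol[1] + drop(W %*% sol[-1])
    expect_lt(max(abs(unname(fit$gebv[names(y)]) - gebv_rr)), 1e-6)
  }
})

test_that("noiseless data is fitted almost perfectly", {
  mk <- random_markers(60, 200, seed = 23)
  K <- compute_kinship(impute_markers(mk))
  sim <- simulate_gblup_y(K, sigma2_G = 1, sigma2_e = 1e-12, seed = 2)
  fit <- fit_gblup(sim$y, K)
  expect_gt(cor(fit$gebv[names(sim$y)], sim$y), 0.999)
})

test_that("prediction of unphenotyped lines matches a dense mixed-model solve", {
  mk <- random_markers(80, 250, seed = 31)
  mk[5, ] <- mk[70, ]  # line 5 duplicates a training line
  K <- compute_kinship(impute_markers(mk))
  sim <- simulate_gblup_y(K, 1, 1, seed = 3)
  train <- rownames(mk)[11:80]
  yt <- sim$y[train]
  fit <- fit_gblup(yt, K)

  expect_identical(predict_new(fit, train), fit$gebv[train])
  expect_error(predict_new(fit, c("L011", "NOPE")), "NOPE")
  # duplicate marker rows receive identical additive effects
  expect_equal(fit$g[["L005"]], fit$g[["L070"]], tolerance = 1e-10)

  # oracle: g_new = K_nt (K_tt + lambda I)^{-1} (y - mu)
  new <- rownames(mk)[1:10]
  lam <- fit$sigma2_e / fit$sigma2_G
  Ktt <- unclass(K)[train, train]
  Vs <- Ktt + diag(lam, length(train))
  Vinv <- solve(Vs)
  mu_gls <- drop(solve(sum(Vinv), sum(Vinv %*% yt)))
  g_new <- drop(unclass(K)[new, train] %*% (Vinv %*% (yt - mu_gls)))
  got <- predict_new(fit, new)
  # both sides centered the same way (fit recentres g on the training mean)
  g_tr <- drop(Ktt %*% (Vinv %*% (yt - mu_gls)))
  expect_equal(unname(got), unname(g_new - mean(g_tr) + fit$mu),
               tolerance = 1e-6)
})

test_that("an extreme fixed PYT residual variance recovers the MET-only fit", {
  sim <- small_sim(seed = 41, n_lines = 120)
  K <- compute_kinship(impute_markers(sim$markers))
  simy <- simulate_gblup_y(K, 1, 0.8, seed = 5)
  met_lines <- rownames(K)[1:80]
  pyt_lines <- rownames(K)[81:120]
  y_met <- simy$y[met_lines]
  fit0 <- fit_gblup(y_met, K)
  set.seed(99)
  rec <- rbind(
    data.frame(line_id = met_lines, value = as.numeric(y_met), group = "MET"),
    data.frame(line_id = pyt_lines,
               value = rnorm(40, 0, 3), group = "PYT"))
  fit1 <- fit_gblup(rec, K, fix_pyt_variance = 1e6 * fit0$sigma2_e)
  expect_lt(max(abs(fit1$gebv - fit0$gebv)), 1e-4)
})

test_that("informative PYT records improve prediction of true breeding values", {
  # directional property over repeated populations: the weighted
  # (genomics-assisted) fit beats the MET-only fit for the candidates
  wins <- 0L
  for (s in 1:30) {
    mk <- random_markers(120, 150, seed = 100 + s)
    K <- compute_kinship(impute_markers(mk))
    set.seed(200 + s)
    ev <- eigen(unclass(K), symmetric = TRUE)
    g <- drop(ev$vectors %*% (sqrt(pmax(ev$values, 0)) * rnorm(120)))
    names(g) <- rownames(mk)
    train <- rownames(mk)[1:80]
    cand <- rownames(mk)[81:120]
    y_met <- g[train] + rnorm(80, 0, 0.7)
    y_pyt <- g[cand] + rnorm(40, 0, 1.4)
    fit_gb <- fit_gblup(y_met, K)
    rec <- rbind(
      data.frame(line_id = train, value = as.numeric(y_met), group = "MET"),
      data.frame(line_id = cand, value = as.numeric(y_pyt), group = "PYT"))
    fit_ga <- fit_gblup(rec, K)
    if (cor(fit_ga$gebv[cand], g[cand]) > cor(fit_gb$gebv[cand], g[cand]))
      wins <- wins + 1L
  }
  expect_gte(wins, 21L)  # >= 70% of 30 populations
})
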