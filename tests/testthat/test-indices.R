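test_that("deviation regression matches the normal equations on a hand dataset", {
  gy <- c(L1 = 60, L2 = 70, L3 = 80, L4 = 90, L5 = 100)
  pc <- c(L1 = 15.2, L2 = 14.9, L3 = 14.1, L4 = 13.4, L5 = 13.6)
  dr <- deviation_regression(pc, gy)
  # independent normal-equations oracle: solve X'X b = X'y directly
  X <- unname(cbind(1, gy))
  ab <- solve(crossprod(X), crossprod(X, pc))
  expect_equal(dr$alpha, ab[1, 1], tolerance = 1e-12)
  expect_equal(dr$beta, ab[2, 1], tolerance = 1e-12)
  expect_equal(unname(dr$residuals), unname(pc - drop(X %*% ab)),
               tolerance = 1e-12)
})

test_that("deviations vanish on exactly collinear traits and are orthogonal otherwise", {
  gy <- seq(60, 100, by = 5)
  names(gy) <- sprintf("L%02d", seq_along(gy))
  pc_lin <- 20 - 0.07 * gy
  dr <- deviation_regression(pc_lin, gy)
  expect_lt(max(abs(dr$residuals)), 1e-12)
  set.seed(2)
  pc <- pc_lin + rnorm(length(gy), 0, 0.4)
  dr2 <- deviation_regression(pc, gy)
  expect_lt(abs(cor(dr2$residuals, gy)), 1e-12)
  expect_error(deviation_regression(pc, rep(1, length(gy))["L01"]), "length")
  expect_error(deviation_regression(pc[1:2], gy[1:2]), "3 lines")
  expect_error(deviation_regression(pc, setNames(rep(1, 9), names(gy))),
               "constant")
})

test_that("restriction weights follow the 2x2 inversion", {
  C <- cov2_matrix(2, 4, 1, traits = c("PC", "GY"))
  def <- restriction_weights(C, name = "GPD")
  expect_equal(def$beta, 0.25)
  expect_equal(unname(def$b), c(1, -0.25))
  # diagonal covariance: no restriction needed
  D <- cov2_matrix(3, 5, 0)
  expect_equal(unname(restriction_weights(D)$b), c(1, 0))
  # scale invariance
  C10 <- cov2_matrix(20, 40, 10, traits = c("PC", "GY"))
  expect_equal(restriction_weights(C10)$b, restriction_weights(C)$b)
  # singular matrix rejected
  S <- matrix(c(4, 4, 4, 4), 2, 2)
  expect_error(restriction_weights(S), "positive definite")
})

test_that("restriction weights reproduce the regression coefficient exactly", {
  set.seed(3)
  gy <- rnorm(40, 80, 5); names(gy) <- sprintf("L%02d", 1:40)
  pc <- 18 - 0.05 * gy + rnorm(40, 0, 0.5); names(pc) <- names(gy)
  dr <- deviation_regression(pc, gy)
  def <- restriction_weights(pheno_cov(pc, gy, c("PC", "GY")))
  expect_equal(def$beta, dr$beta, tolerance = 1e-12)
})

test_that("the GEBV covariance matrix matches a scalar-loop oracle", {
  set.seed(4)
  v1 <- rnorm(10); names(v1) <- sprintf("L%02d", 1:10)
  v2 <- rnorm(10); names(v2) <- names(v1)
  C <- gebv_cov(v1, v2, traits = c("GY", "PC"))
  n <- 10
  m1 <- sum(v1) / n; m2 <- sum(v2) / n
  s11 <- s22 <- s12 <- 0
  for (i in 1:n) {
    s11 <- s11 + (v1[i] - m1)^2
    s22 <- s22 + (v2[i] - m2)^2
    s12 <- s12 + (v1[i] - m1) * (v2[i] - m2)
  }
  expect_equal(C[1, 1], unname(s11 / (n - 1)), tolerance = 1e-12)
  expect_equal(C[2, 2], unname(s22 / (n - 1)), tolerance = 1e-12)
  expect_equal(C[1, 2], unname(s12 / (n - 1)), tolerance = 1e-12)
  expect_equal(attr(C, "source"), "genomic")
  # identical and mirrored inputs
  expect_equal(gebv_cov(v1, v1)[1, 2], var(v1))
  expect_equal(gebv_cov(v1, -v1)[1, 2], -var(v1))
  expect_error(gebv_cov(v1, setNames(v2, rev(sprintf("X%02d", 1:10)))),
               "mismatched")
})

test_that("index scores follow the restriction form and rank like the deviations", {
  gy <- c(A = 70, B = 80, C = 90, D = 100)
  pc <- c(A = 15, B = 14, C = 14.5, D = 13)
  def <- list(name = "GPD", beta = 0.5, source = "phenotypic")
  sc <- compute_index(def, pc, gy)
  expect_equal(sc$score, pc - 0.5 * gy, ignore_attr = TRUE)
  # beta = 0: scores equal the primary values
  sc0 <- compute_index(list(name = "x", beta = 0), pc, gy)
  expect_equal(sc0$score, unname(pc))
  # same beta source: index scores and regression residuals rank identically
  dr <- deviation_regression(pc, gy)
  sc1 <- compute_index(list(name = "GPD", beta = dr$beta), pc, gy)
  expect_equal(cor(sc1$score, dr$residuals, method = "spearman"), 1)
  expect_equal(sc1$score - mean(sc1$score),
               unname(dr$residuals - mean(dr$residuals)), tolerance = 1e-12)
  expect_error(compute_index(list(name = "n"), pc, gy), "beta")
})

test_that("every restriction index is uncorrelated with its restricted trait", {
  set.seed(6)
  n <- 80
  ids <- sprintf("L%03d", 1:n)
  gy <- setNames(rnorm(n, 80, 5), ids)
  pc <- setNames(18 - 0.06 * gy + rnorm(n, 0, 0.5), ids)
  py <- gy * pc / 100
  vals <- list(GY = gy, PC = pc, PY = py)
  roles <- index_roles()
  for (i in seq_len(nrow(roles))) {
    C <- pheno_cov(vals[[roles$primary[i]]], vals[[roles$secondary[i]]],
                   c(roles$primary[i], roles$secondary[i]))
    def <- restriction_weights(C, name = roles$index[i])
    sc <- compute_index(def, vals[[roles$primary[i]]],
                        vals[[roles$secondary[i]]])
    expect_lt(abs(cor(sc$score, vals[[roles$secondary[i]]])), 1e-10)
  }
})
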