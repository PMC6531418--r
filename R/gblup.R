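#' Fit a GBLUP model
#'
#' Mixed model \eqn{y = Xb + Zg + e} with line effects
#' \eqn{g \sim N(0, K\sigma^2_G)} distributed according to the genomic
#' relationship matrix, solved by REML.  Two variance structures are
#' supported:
#' \itemize{
#'   \item homogeneous residuals (one record per line): the profile
#'     restricted likelihood of the variance ratio
#'     \eqn{\lambda = \sigma^2_e / \sigma^2_G} is maximised exactly on the
#'     eigendecomposition of K (deterministic 1-D optimisation);
#'   \item heterogeneous residuals: records carry a group label (`"MET"`
#'     or `"PYT"`), lines may appear once per group, a common residual
#'     variance is estimated per group, and the fixed effects comprise the
#'     grand mean plus a PYT-stage indicator.  The restricted likelihood
#'     is maximised by bounded quasi-Newton iteration on the
#'     log-variances.
#' }
#' The latter structure is the genomics-assisted model: multi-environment
#' BLUEs of the training lines plus the selection candidates' own (noisy)
#' preliminary-yield-trial records, downweighted through their larger
#' residual variance.
#'
#' GEBVs are defined as \eqn{GEBV_i = \mu + g_i} and returned for every
#' line in K, including unphenotyped lines (predicted through their
#' genomic relationship with the phenotyped lines).  The additive effects
#' are reported as deviations from their mean over the phenotyped lines
#' (the mean is absorbed into \eqn{\mu}), so `mean(g)` over the training
#' lines is zero by construction.
#'
#' @param y either a named numeric vector of per-line BLUEs (one record
#'   per line) or a data frame with columns `line_id`, `value` and
#'   optionally `group` (values `"MET"`/`"PYT"`).
#' @param K genomic relationship matrix ([compute_kinship()]) covering at
#'   least all phenotyped lines.
#' @param groups optional character vector of record groups, an
#'   alternative to the `group` column.
#' @param fix_pyt_variance optional fixed value for the PYT residual
#'   variance (otherwise estimated).
#' @param trait optional trait label stored in the result.
#' @return an object of class `gblup`: list with `gebv` (named, all K
#'   lines), `g`, `mu`, `beta` (fixed effects), `sigma2_G`, `sigma2_e`
#'   (named per group when heterogeneous), `lambda`, `reml_loglik`,
#'   `trained` (phenotyped line ids), `trait`.
#' @examples
#' set.seed(1)
#' Z <- matrix(sample(c(-1L, 1L), 50 * 80, TRUE), 50, 80,
#'             dimnames = list(sprintf("L%02d", 1:50), sprintf("M%02d", 1:80)))
#' K <- compute_kinship(impute_markers(Z))
#' g <- drop(Z %*% rnorm(80, 0, 0.2))
#' y <- g + rnorm(50)
#' names(y) <- rownames(Z)
#' fit <- fit_gblup(y, K)
#' cor(fit$gebv, g)
#' @export
fit_gblup <- function(y, K, groups = NULL, fix_pyt_variance = NULL,
                      trait = NULL) {
  rec <- .as_records(y, groups)
  K <- .check_kinship(K, rec$line_id)
  ulines <- unique(rec$line_id)
  map <- match(rec$line_id, ulines)
  kin_idx <- match(ulines, rownames(K))

  two_groups <- length(unique(rec$group)) > 1L
  if (!two_groups && !anyDuplicated(rec$line_id) && is.null(fix_pyt_variance))
    return(.fit_gblup_eigen(rec, K, kin_idx, trait))
  .fit_gblup_general(rec, K, ulines, map, kin_idx, fix_pyt_variance, trait)
}

.as_records <- function(y, groups) {
  if (is.data.frame(y)) {
    if (!all(c("line_id", "value") %in% names(y)))
      stop_selix("record data frame needs columns line_id and value")
    grp <- if (!is.null(groups)) groups
           else if ("group" %in% names(y)) y$group else rep("MET", nrow(y))
    rec <- data.frame(line_id = as.character(y$line_id), value = y$value,
                      group = grp, stringsAsFactors = FALSE)
  } else {
    if (is.null(names(y)))
      stop_selix("'y' must be a named vector or a record data frame")
    rec <- data.frame(line_id = names(y), value = as.numeric(y),
                      group = if (is.null(groups)) "MET" else groups,
                      stringsAsFactors = FALSE)
  }
  if (!all(rec$group %in% c("MET", "PYT")))
    stop_selix("record groups must be 'MET' or 'PYT'")
  if (anyDuplicated(rec[c("line_id", "group")]))
    stop_selix("at most one record per line and group is supported")
  if (anyNA(rec$value)) stop_selix("missing values in y")
  rec
}

.check_kinship <- function(K, line_id) {
  if (!is.matrix(K) || is.null(rownames(K)))
    stop_selix("'K' must be a matrix with line ids as dimnames")
  missing <- setdiff(unique(line_id), rownames(K))
  if (length(missing))
    stop_selix("phenotyped lines absent from K: ",
               paste(utils::head(missing, 5), collapse = ", "))
  K
}

# homogeneous residuals, one record per line: exact 1-D profile REML on
# the eigendecomposition of K
.fit_gblup_eigen <- function(rec, K, kin_idx, trait, eig = NULL) {
  yv <- rec$value
  n <- length(yv)
  Ksub <- unclass(K)[kin_idx, kin_idx, drop = FALSE]
  if (is.null(eig)) eig <- eigen(Ksub, symmetric = TRUE)
  d <- eig$values
  if (min(d) < -1e-8 * max(abs(d))) {
    warning("K is not positive semi-definite; ridge-stabilizing with 1e-6",
            call. = FALSE)
    d <- d + 1e-6
  }
  d <- pmax(d, 0)
  U <- eig$vectors
  X <- matrix(1, n, 1)
  yt <- crossprod(U, yv)
  Xt <- crossprod(U, X)
  p <- 1L

  dev <- function(loglam) {
    lam <- exp(loglam)
    w <- 1 / (d + lam)
    B <- sum(w * Xt^2)
    bh <- sum(w * Xt * yt) / B
    r <- yt - Xt * bh
    s2g <- sum(w * r^2) / (n - p)
    (n - p) * log(s2g) + sum(log(d + lam)) + log(B)
  }
  opt <- stats::optimize(dev, c(-25, 25), tol = 1e-10)
  lam <- exp(opt$minimum)
  w <- 1 / (d + lam)
  B <- sum(w * Xt^2)
  bh <- sum(w * Xt * yt) / B
  r <- yt - Xt * bh
  s2g <- sum(w * r^2) / (n - p)
  s2e <- lam * s2g

  # BLUP of g for every line in K
  u <- U %*% (r * w / s2g)          # = V^{-1} (y - X b)
  ghat <- drop(s2g * unclass(K)[, kin_idx, drop = FALSE] %*% u)
  names(ghat) <- rownames(K)
  c0 <- mean(ghat[kin_idx])
  g <- ghat - c0
  mu <- bh + c0

  structure(list(
    gebv = mu + g, g = g, mu = mu, beta = c(intercept = bh),
    sigma2_G = s2g, sigma2_e = s2e, lambda = lam,
    reml_loglik = -0.5 * opt$objective,
    trained = rec$line_id, trait = trait), class = "gblup")
}

# heterogeneous residual variances (or repeated lines): bounded
# quasi-Newton REML on log-variances
.fit_gblup_general <- function(rec, K, ulines, map, kin_idx,
                               fix_pyt_variance, trait) {
  yv <- rec$value
  n <- length(yv)
  Ksub <- unclass(K)[kin_idx, kin_idx, drop = FALSE]
  ev_min <- min(eigen(Ksub, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8 * max(abs(diag(Ksub)))) {
    warning("K is not positive semi-definite; ridge-stabilizing with 1e-6",
            call. = FALSE)
    Ksub <- Ksub + diag(1e-6, nrow(Ksub))
  }
  ZKZt <- Ksub[map, map, drop = FALSE]

  grp_levels <- sort(unique(rec$group))
  gidx <- match(rec$group, grp_levels)
  two_groups <- length(grp_levels) > 1L
  X <- if (two_groups) cbind(intercept = 1, pyt = as.numeric(rec$group == "PYT"))
       else matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  p <- ncol(X)

  est_groups <- if (is.null(fix_pyt_variance)) grp_levels
                else setdiff(grp_levels, "PYT")
  vy <- stats::var(yv)

  make_s2e <- function(par) {
    s2e <- numeric(length(grp_levels))
    names(s2e) <- grp_levels
    s2e[est_groups] <- exp(par[-1])
    if (!is.null(fix_pyt_variance)) s2e["PYT"] <- fix_pyt_variance
    s2e
  }
  dev <- function(par) {
    s2g <- exp(par[1])
    s2e <- make_s2e(par)
    V <- s2g * ZKZt
    diag(V) <- diag(V) + s2e[gidx]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    Ly <- backsolve(ch, yv, transpose = TRUE)
    LX <- backsolve(ch, X, transpose = TRUE)
    B <- crossprod(LX)
    cB <- tryCatch(chol(B), error = function(e) NULL)
    if (is.null(cB)) return(1e10)
    Xy <- crossprod(LX, Ly)
    bh <- backsolve(cB, forwardsolve(t(cB), Xy))
    quad <- sum(Ly^2) - sum(Xy * bh)
    2 * sum(log(diag(ch))) + 2 * sum(log(diag(cB))) + quad
  }

  par0 <- log(c(vy / 2, rep(vy / 2, length(est_groups))))
  opt <- stats::optim(par0, dev, method = "L-BFGS-B",
                      lower = log(vy * 1e-8), upper = log(vy * 1e8),
                      control = list(factr = 1e7, maxit = 200))
  if (opt$convergence != 0) {
    # line searches can abort on near-flat restricted likelihoods;
    # restart with a simplex from the best point found so far
    opt2 <- stats::optim(opt$par, dev, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-12))
    if (opt2$convergence != 0 || opt2$value > opt$value + 1e-6)
      stop_selix(sprintf(
        "REML did not converge (L-BFGS-B code %d after %d evaluations: %s; simplex restart code %d after %d evaluations)",
        opt$convergence, opt$counts[1], opt$message %||% "",
        opt2$convergence, opt2$counts[1]))
    opt <- opt2
  }
  s2g <- exp(opt$par[1])
  s2e <- make_s2e(opt$par)

  V <- s2g * ZKZt
  diag(V) <- diag(V) + s2e[gidx]
  ch <- chol(V)
  Ly <- backsolve(ch, yv, transpose = TRUE)
  LX <- backsolve(ch, X, transpose = TRUE)
  B <- crossprod(LX)
  bh <- drop(solve(B, crossprod(LX, Ly)))
  names(bh) <- colnames(X)
  u <- backsolve(ch, backsolve(ch, yv - X %*% bh, transpose = TRUE))
  tZu <- rowsum(as.vector(u), map)        # ordered by line index 1..L
  ghat <- drop(s2g * unclass(K)[, kin_idx, drop = FALSE] %*% tZu)
  names(ghat) <- rownames(K)
  c0 <- mean(ghat[kin_idx])
  g <- ghat - c0
  mu <- bh[["intercept"]] + c0

  if (!two_groups) s2e <- unname(s2e[1])
  structure(list(
    gebv = mu + g, g = g, mu = mu, beta = bh,
    sigma2_G = s2g, sigma2_e = s2e,
    lambda = if (two_groups) NA_real_ else s2e / s2g,
    reml_loglik = -0.5 * opt$value,
    trained = unique(rec$line_id), trait = trait), class = "gblup")
}

#' @export
print.gblup <- function(x, ...) {
  cat(sprintf("GBLUP fit%s: %d phenotyped lines, %d lines with GEBVs\n",
              if (!is.null(x$trait)) paste0(" (", x$trait, ")") else "",
              length(x$trained), length(x$gebv)))
  cat(sprintf("  mu = %.4f, sigma2_G = %.4f, sigma2_e = %s\n",
              x$mu, x$sigma2_G,
              paste(sprintf("%.4f", x$sigma2_e), collapse = " / ")))
  invisible(x)
}

#' Extract GEBVs for target lines
#'
#' Returns \eqn{GEBV = \mu + g} for the requested lines from a fitted
#' GBLUP model; target lines must have been present in K at fit time
#' (phenotyped or not).
#'
#' @param fit a [fit_gblup()] object.
#' @param target_lines character vector of line ids.
#' @return named numeric vector of GEBVs.
#' @export
predict_new <- function(fit, target_lines) {
  if (!inherits(fit, "gblup")) stop_selix("'fit' must be a gblup object")
  unknown <- setdiff(target_lines, names(fit$gebv))
  if (length(unknown))
    stop_selix("unknown line ids: ", paste(unknown, collapse = ", "))
  fit$gebv[target_lines]
}
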