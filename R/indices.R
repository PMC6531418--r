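#' Deviations from the yield/protein regression
#'
#' Ordinary least-squares regression of a primary trait on a secondary
#' trait; the residuals are the deviation scores.  With protein content
#' as primary and grain yield as secondary this yields the grain protein
#' deviation (GPD), flagging lines with more protein than their yield
#' predicts; with the roles swapped it yields the grain yield deviation
#' (GYD).  Deviations are computed on per-line BLUEs.
#'
#' @param primary named numeric vector of per-line values of the improved
#'   trait.
#' @param secondary named numeric vector of per-line values of the
#'   regressor trait (same lines).
#' @return list with `alpha` (intercept), `beta` (slope) and `residuals`
#'   (named deviation scores, in primary-trait units).
#' @export
deviation_regression <- function(primary, secondary) {
  if (length(primary) != length(secondary))
    stop_selix("primary and secondary must have equal length")
  if (!is.null(names(primary)) && !is.null(names(secondary))) {
    if (!setequal(names(primary), names(secondary)))
      stop_selix("primary and secondary must cover the same lines")
    secondary <- secondary[names(primary)]
  }
  if (length(primary) < 3L)
    stop_selix("at least 3 lines are required")
  vs <- stats::var(secondary)
  if (vs == 0)
    stop_selix("secondary trait is constant; regression undefined")
  beta <- stats::cov(primary, secondary) / vs
  alpha <- mean(primary) - beta * mean(secondary)
  res <- primary - alpha - beta * secondary
  list(alpha = unname(alpha), beta = unname(beta), residuals = res)
}

#' Two-trait variance-covariance matrix
#'
#' Container for the 2 x 2 phenotypic or genomic variance-covariance
#' matrix used to derive restriction-index weights.
#'
#' @param var_primary variance of the primary (improved) trait.
#' @param var_secondary variance of the secondary (restricted) trait.
#' @param cov covariance between the traits.
#' @param traits character vector `c(primary, secondary)`.
#' @param source `"phenotypic"` or `"genomic"`.
#' @return an object of class `cov2` (a 2 x 2 matrix with attributes).
#' @export
cov2_matrix <- function(var_primary, var_secondary, cov,
                        traits = c("primary", "secondary"),
                        source = c("phenotypic", "genomic")) {
  source <- match.arg(source)
  if (var_primary <= 0 || var_secondary <= 0)
    stop_selix("variances must be positive")
  if (abs(cov) > sqrt(var_primary * var_secondary))
    stop_selix("|cov| exceeds sqrt(var_primary * var_secondary)")
  C <- matrix(c(var_primary, cov, cov, var_secondary), 2, 2,
              dimnames = list(traits, traits))
  attr(C, "source") <- source
  class(C) <- c("cov2", class(C))
  C
}

#' Phenotypic variance-covariance matrix from per-line values
#'
#' Sample variances and covariance of two per-line value vectors
#' (typically across-trial BLUEs), tagged as phenotypic.
#'
#' @inheritParams deviation_regression
#' @param traits character vector `c(primary, secondary)`.
#' @return a [cov2_matrix()] object.
#' @export
pheno_cov <- function(primary, secondary, traits = c("primary", "secondary")) {
  if (!is.null(names(primary)) && !is.null(names(secondary)))
    secondary <- secondary[names(primary)]
  cov2_matrix(stats::var(primary), stats::var(secondary),
              stats::cov(primary, secondary), traits, "phenotypic")
}

#' Genomic variance-covariance matrix from GEBVs
#'
#' Sample variances of the two GEBV vectors on the diagonal and their
#' sample covariance off-diagonal, the computationally cheapest genomic
#' variance-covariance estimate for index weights in large breeding
#' datasets.
#'
#' @param bv1 GEBVs of the primary trait: a [fit_gblup()] object or a
#'   named numeric vector.
#' @param bv2 GEBVs of the secondary trait on the same line set.
#' @param traits character vector `c(primary, secondary)`.
#' @return a [cov2_matrix()] object with source `"genomic"`.
#' @export
gebv_cov <- function(bv1, bv2, traits = c("primary", "secondary")) {
  v1 <- if (inherits(bv1, "gblup")) bv1$gebv else bv1
  v2 <- if (inherits(bv2, "gblup")) bv2$gebv else bv2
  if (is.null(names(v1)) || is.null(names(v2)))
    stop_selix("GEBV vectors must be named by line id")
  if (!setequal(names(v1), names(v2)))
    stop_selix("mismatched line sets between the two GEBV sets")
  v2 <- v2[names(v1)]
  cov2_matrix(stats::var(v1), stats::var(v2), stats::cov(v1, v2),
              traits, "genomic")
}

#' Restriction-index weights from a variance-covariance matrix
#'
#' Solves \eqn{b = C^{-1} a} for the desired-gain vector
#' \eqn{a = (1, 0)^T} (improve the primary trait, hold the secondary
#' trait's expected change at zero) and rescales so the primary-trait
#' weight is exactly 1, giving \eqn{b = (1, -\beta)^T} with
#' \eqn{\beta = cov / var_{secondary}} -- the regression coefficient of
#' the primary on the secondary trait.
#'
#' @param C a [cov2_matrix()] (phenotypic or genomic), positive definite.
#' @param a desired-gain vector (default `c(1, 0)`).
#' @param name index name (e.g. `"GPD"`, `"GYD"`, `"HP"`, `"HY"`).
#' @return an object of class `index_definition`: list with `name`,
#'   `primary`, `secondary`, `a`, `b`, `beta`, `source`.
#' @export
restriction_weights <- function(C, a = c(1, 0), name = "index") {
  if (!is.matrix(C) || any(dim(C) != 2L))
    stop_selix("'C' must be a 2 x 2 matrix")
  dt <- det(C)
  if (!is.finite(dt) || dt <= 0 || C[1, 1] <= 0)
    stop_selix("'C' must be positive definite")
  b <- unname(solve(unclass(C), a))
  if (b[1] == 0)
    stop_selix("primary-trait weight is zero; cannot rescale")
  b <- b / b[1]
  traits <- rownames(C) %||% c("primary", "secondary")
  names(b) <- traits
  structure(list(
    name = name, primary = traits[1], secondary = traits[2],
    a = a, b = b, beta = unname(-b[2]),
    source = attr(C, "source") %||% "phenotypic"),
    class = "index_definition")
}

#' @export
print.index_definition <- function(x, ...) {
  cat(sprintf("Restriction index %s (%s): improve %s, restrict %s\n",
              x$name, x$source, x$primary, x$secondary))
  cat(sprintf("  b = (1, %.4f), beta = %.4f\n", x$b[2], x$beta))
  invisible(x)
}

#' Trait roles of the four named restriction indices
#'
#' GPD improves protein content holding grain yield (high-protein lines
#' with acceptable yield); GYD improves grain yield holding protein
#' content; HP improves protein yield holding grain yield (protein yield
#' via protein content); HY improves protein yield holding protein
#' content (protein yield via grain yield).
#'
#' @return data frame with columns `index`, `primary`, `secondary`.
#' @export
index_roles <- function() {
  data.frame(index = c("GPD", "GYD", "HP", "HY"),
             primary = c("PC", "GY", "PY", "PY"),
             secondary = c("GY", "PC", "GY", "PC"),
             stringsAsFactors = FALSE)
}

#' Compute restriction-index scores
#'
#' Scores are \eqn{primary - \beta \times secondary} in primary-trait
#' units; they differ from the corresponding regression deviations only
#' by the regression intercept and therefore rank lines identically.
#'
#' @param def an [restriction_weights()] index definition (or any list
#'   with elements `beta` and `name`).
#' @param primary_values named per-line values of the improved trait.
#' @param secondary_values named per-line values of the restricted trait
#'   (same lines).
#' @return data frame of class `index_scores` with columns `line_id`,
#'   `index_name`, `score`, `beta`, `source`.
#' @export
compute_index <- function(def, primary_values, secondary_values) {
  if (is.null(def$beta) || is.na(def$beta))
    stop_selix("index definition has no beta")
  if (!is.null(names(primary_values)) && !is.null(names(secondary_values))) {
    if (!setequal(names(primary_values), names(secondary_values)))
      stop_selix("primary and secondary values must cover the same lines")
    secondary_values <- secondary_values[names(primary_values)]
  } else if (length(primary_values) != length(secondary_values))
    stop_selix("primary and secondary values must have equal length")
  sc <- unname(primary_values) - def$beta * unname(secondary_values)
  out <- data.frame(
    line_id = names(primary_values) %||% as.character(seq_along(primary_values)),
    index_name = def$name %||% "index",
    score = unname(sc),
    beta = def$beta,
    source = def$source %||% NA_character_,
    stringsAsFactors = FALSE)
  class(out) <- c("index_scores", class(out))
  out
}

# named score vector from index_scores (or pass-through for named vectors)
score_vector <- function(x) {
  if (inherits(x, "index_scores") || (is.data.frame(x) && "score" %in% names(x)))
    stats::setNames(x$score, x$line_id)
  else x
}

#' Write index scores to CSV
#'
#' Columns `line_id, index_name, score, beta, source`, floating point at
#' 8 significant digits.
#'
#' @param scores an [compute_index()] result (or rbind of several).
#' @param path output CSV path.
#' @export
write_index_scores <- function(scores, path) {
  scores$score <- signif(scores$score, 8)
  scores$beta <- signif(scores$beta, 8)
  utils::write.csv(scores, path, row.names = FALSE, quote = FALSE)
  invisible(scores)
}
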