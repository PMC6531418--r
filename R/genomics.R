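#' Marker quality control
#'
#' Removes markers failing any of the standard thresholds: call rate
#' below `call_rate` (default 0.90), minor allele frequency strictly
#' below `maf_min` (default 0.05; a MAF of exactly 0.05 is retained), or
#' missing-data fraction strictly above `max_missing` (default 0.10).
#' Allele frequencies are computed from the observed codes as the mean of
#' `(code + 1) / 2`.
#'
#' @param markers lines x markers matrix coded -1/0/1 with `NA` for
#'   missing calls; dimnames required.
#' @param call_rate minimum call rate.
#' @param maf_min minimum minor allele frequency.
#' @param max_missing maximum missing fraction.
#' @return the filtered matrix, with an attribute `qc_report` (named
#'   integer vector of removal counts per criterion and markers kept).
#' @export
qc_markers <- function(markers, call_rate = 0.90, maf_min = 0.05,
                       max_missing = 0.10) {
  .check_codes(markers)
  miss <- colMeans(is.na(markers))
  p <- colMeans((markers + 1) / 2, na.rm = TRUE)
  maf <- pmin(p, 1 - p)
  low_call <- (1 - miss) < call_rate
  low_maf <- maf < maf_min
  too_missing <- miss > max_missing
  drop <- low_call | low_maf | too_missing
  if (all(drop))
    stop_selix("all markers removed by quality control")
  out <- markers[, !drop, drop = FALSE]
  attr(out, "qc_report") <- c(
    low_call_rate = sum(low_call),
    low_maf = sum(low_maf),
    too_missing = sum(too_missing),
    removed = sum(drop),
    kept = sum(!drop))
  out
}

.check_codes <- function(markers) {
  if (!is.matrix(markers) || is.null(rownames(markers)) ||
      is.null(colnames(markers)))
    stop_selix("'markers' must be a lines x markers matrix with dimnames")
  v <- markers[!is.na(markers)]
  if (!all(v %in% c(-1, 0, 1)))
    stop_selix("marker codes must be -1, 0, 1 or NA")
  invisible(TRUE)
}

#' Mean imputation of missing marker calls
#'
#' Replaces each missing code by the per-marker mean of the observed
#' codes; fractional codes are allowed downstream (kinship, ridge
#' regression).
#'
#' @param markers post-QC lines x markers matrix coded -1/0/1/`NA`.
#' @return numeric matrix without missing values.
#' @export
impute_markers <- function(markers) {
  .check_codes(markers)
  nobs <- colSums(!is.na(markers))
  if (any(nobs == 0L))
    stop_selix("markers with zero observed calls cannot be imputed: ",
               paste(colnames(markers)[nobs == 0L], collapse = ", "))
  out <- markers
  storage.mode(out) <- "double"
  cm <- colMeans(out, na.rm = TRUE)
  idx <- which(is.na(out), arr.ind = TRUE)
  if (nrow(idx)) out[idx] <- cm[idx[, 2]]
  out
}

#' Genomic relationship matrix
#'
#' Computes the marker-based kinship
#' \deqn{K = W W^T / (2 \sum_k p_k (1 - p_k))}
#' with the column-centered matrix \eqn{W_{ik} = Z_{ik} + 1 - 2 p_k},
#' genotype codes \eqn{Z \in \{-1, 0, 1\}} (fractional imputed codes
#' allowed), and sample allele frequencies \eqn{p_k} computed as the mean
#' of \eqn{(Z_{ik} + 1)/2}.  Because W is column-centered at the sample
#' frequencies, the row sums of K are zero.
#'
#' @param markers imputed lines x markers matrix (no missing values), at
#'   least two polymorphic markers.
#' @return a `kinship` object: symmetric lines x lines matrix with
#'   attribute `scaling` \eqn{c = 2\sum p_k(1-p_k)}.
#' @export
compute_kinship <- function(markers) {
  if (any(is.na(markers)))
    stop_selix("markers must be imputed before computing kinship")
  p <- colMeans((markers + 1) / 2)
  poly <- p > 0 & p < 1
  if (sum(poly) < 2L)
    stop_selix("kinship undefined: fewer than 2 polymorphic markers ",
               "(zero scaling denominator)")
  W <- sweep(markers + 1, 2L, 2 * p, `-`)
  c0 <- 2 * sum(p * (1 - p))
  K <- tcrossprod(W) / c0
  K <- (K + t(K)) / 2
  attr(K, "scaling") <- c0
  class(K) <- c("kinship", class(K))
  K
}

#' @export
print.kinship <- function(x, ...) {
  cat(sprintf("Genomic relationship matrix: %d lines, scaling c = %.4f\n",
              nrow(x), attr(x, "scaling")))
  cat(sprintf("  mean diagonal %.3f, range of off-diagonal [%.3f, %.3f]\n",
              mean(diag(x)), min(x[upper.tri(x)]), max(x[upper.tri(x)])))
  invisible(x)
}
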