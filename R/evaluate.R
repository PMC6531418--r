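#' Genomic heritability of a validation population
#'
#' Fits a GBLUP model containing only the validation population's own
#' phenotypes and combines its REML residual variance with the phenotypic
#' variance of the observed values:
#' \deqn{h^2_{GEN} = (\sigma^2_P - \sigma^2_e) / \sigma^2_P}
#' clamped to [0, 1] (the estimate can leave the unit interval in small
#' samples; clamping keeps the selected-mean predictor a contraction).
#'
#' @param y named numeric vector of the validation lines' phenotypic
#'   values (at least 10 lines).
#' @param K genomic relationship matrix covering the validation lines.
#' @return the genomic heritability (numeric scalar) with attributes
#'   `sigma2_P` and `sigma2_e`.
#' @export
genomic_heritability <- function(y, K) {
  if (length(y) < 10L)
    stop_selix("genomic heritability requires at least 10 lines")
  fit <- fit_gblup(y, K)
  s2P <- stats::var(y)
  h2 <- (s2P - fit$sigma2_e) / s2P
  if (h2 < 0 || h2 > 1)
    warning(sprintf("genomic heritability %.3f clamped to [0, 1]", h2),
            call. = FALSE)
  structure(clamp01(h2), sigma2_P = s2P, sigma2_e = fit$sigma2_e)
}

#' Heritability-corrected prediction accuracy
#'
#' Pearson correlation between predicted and observed values divided by
#' the square root of the genomic heritability of the observed trait.
#'
#' @param predicted named numeric vector of predictions.
#' @param observed named numeric vector of observed values (same lines).
#' @param h2_gen genomic heritability of the observed trait, in (0, 1].
#' @return the accuracy; `NA` (with a warning) when `h2_gen` is zero.
#' @export
prediction_accuracy <- function(predicted, observed, h2_gen) {
  if (!is.null(names(predicted)) && !is.null(names(observed)))
    observed <- observed[names(predicted)]
  if (length(predicted) != length(observed))
    stop_selix("predicted and observed must cover the same lines")
  if (is.na(h2_gen) || h2_gen <= 0) {
    warning("accuracy undefined for zero genomic heritability", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(predicted, observed) / sqrt(h2_gen)
}

#' Predicted mean of the selected fraction
#'
#' \deqn{\hat\mu_{Sel} = \mu + h^2_{GEN} (\mu_{Sel} - \mu)}
#' the selection differential regressed towards the population mean by
#' the genomic heritability.
#'
#' @param population_mean mean of the entire validation population.
#' @param selected_mean mean of the selected lines.
#' @param h2_gen genomic heritability in [0, 1].
#' @return predicted selected mean (trait units).
#' @export
predict_selected_mean <- function(population_mean, selected_mean, h2_gen) {
  if (is.na(h2_gen) || h2_gen < 0 || h2_gen > 1)
    stop_selix("h2_gen must lie in [0, 1]")
  population_mean + h2_gen * (selected_mean - population_mean)
}

#' Predicted relative response to selection
#'
#' \deqn{R_{Rel} = (\hat\mu_{Sel} - \mu) / \mu} reported in percent.
#'
#' @param mu_sel_hat predicted selected mean ([predict_selected_mean()]).
#' @param mu population mean (nonzero).
#' @return relative response in percent.
#' @export
relative_response <- function(mu_sel_hat, mu) {
  if (any(mu == 0)) stop_selix("population mean is zero; relative response undefined")
  100 * (mu_sel_hat - mu) / mu
}

#' Select the best-performing fraction
#'
#' Top \eqn{\lceil fraction \times n \rceil} lines by score, descending;
#' ties are broken by ascending line id (stable and reproducible).
#'
#' @param scores named numeric vector or [compute_index()] scores.
#' @param fraction selected fraction in (0, 1].
#' @return character vector of selected line ids.
#' @export
select_top <- function(scores, fraction) {
  s <- score_vector(scores)
  if (!length(s)) stop_selix("empty scores")
  if (is.na(fraction) || fraction <= 0 || fraction > 1)
    stop_selix("fraction must lie in (0, 1]")
  ids <- names(s) %||% as.character(seq_along(s))
  k <- .ceil_frac(fraction, length(s))
  ord <- order(-s, ids)
  ids[ord][seq_len(k)]
}

# ceiling(fraction * n) guarded against floating-point overshoot
.ceil_frac <- function(fraction, n) as.integer(ceiling(fraction * n - 1e-9))

#' Combined two-index selection
#'
#' Splits the selection decision into two halves: the top
#' `fraction / 2` lines by a protein-oriented index united with the top
#' `fraction / 2` lines by a yield-oriented index.  Overlap between the
#' two half-lists is resolved by extending the yield-index list until the
#' union reaches `ceiling(fraction * n)` lines, so the selected set has a
#' fixed size.
#'
#' @param protein_scores scores of the protein-oriented index (GPD or HP).
#' @param yield_scores scores of the yield-oriented index (GYD or HY) on
#'   the same candidates.
#' @param fraction total selected fraction (default 0.10, i.e. 5% + 5%).
#' @return character vector of selected line ids.
#' @export
combined_selection <- function(protein_scores, yield_scores, fraction = 0.10) {
  sp <- score_vector(protein_scores)
  sy <- score_vector(yield_scores)
  if (!setequal(names(sp), names(sy)))
    stop_selix("both indices must score the same candidates")
  n <- length(sp)
  target <- .ceil_frac(fraction, n)
  half <- .ceil_frac(fraction / 2, n)
  ids_p <- names(sp)[order(-sp, names(sp))]
  sel_p <- ids_p[seq_len(half)]
  ids_y <- names(sy)[order(-sy, names(sy))]
  sel <- unique(c(sel_p, ids_y[seq_len(half)]))
  i <- half
  while (length(sel) < target && i < n) {
    i <- i + 1L
    sel <- unique(c(sel, ids_y[i]))
  }
  sel
}
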