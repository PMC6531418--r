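#' Per-trial BLUEs and repeatability
#'
#' First stage of the two-stage phenotypic analysis.  For a single trial
#' and trait, fits a fixed-effects model with line and replicate effects
#' (iid residuals) to obtain best linear unbiased estimates (BLUEs) per
#' line, and a companion model with random line effects (REML) to estimate
#' the genetic variance.  The repeatability is
#' \deqn{h^2 = \sigma^2_G / (\sigma^2_G + \tfrac{1}{2} MVD)}
#' where MVD is the mean variance of a difference of two line BLUEs.
#'
#' For unreplicated designs (typically preliminary yield trials, where
#' only check varieties are replicated) the genetic variance and thus the
#' repeatability are not estimable: BLUEs are then returned as
#' check-adjusted values (line mean minus the trial's check mean, or minus
#' the trial mean when no replicated checks exist), `h2` is `NA`, and a
#' warning flags the unestimable repeatability.
#'
#' @param plots long-format plot records of a single trial and trait:
#'   data frame with columns `line_id`, `trial_id`, `trait`, `replicate`,
#'   `value` (and optionally `stage`, `year`).
#' @return an object of class `trial_summary`: list with elements
#'   `trial_id`, `trait`, `blues` (named vector), `sigma2_G`, `MVD`, `h2`,
#'   `n_lines`, and `note` (character, `NA` unless repeatability was
#'   unestimable).
#' @seealso [filter_trials()], [combine_trials()]
#' @export
trial_blues <- function(plots) {
  req <- c("line_id", "trial_id", "trait", "replicate", "value")
  miss <- setdiff(req, names(plots))
  if (length(miss))
    stop_selix("missing phenotype columns: ", paste(miss, collapse = ", "))
  trial <- unique(plots$trial_id)
  trait <- unique(plots$trait)
  if (length(trial) != 1L || length(trait) != 1L)
    stop_selix("trial_blues() expects records of exactly one trial and one trait")
  if (anyDuplicated(plots[c("line_id", "replicate")]))
    stop_selix("duplicated (line_id, replicate) records in trial ", trial)
  tab <- table(plots$line_id)
  if (length(tab) < 2L)
    stop_selix("trial ", trial, " has fewer than 2 lines")

  if (any(tab == 1L)) {
    # unreplicated entries: repeatability unestimable
    checks <- names(tab)[tab > 1L]
    line_means <- c(tapply(plots$value, plots$line_id, mean))
    adj <- if (length(checks)) mean(plots$value[plots$line_id %in% checks])
           else mean(plots$value)
    blues <- line_means - adj
    warning(sprintf(
      "unestimable repeatability in trial %s (%s): unreplicated entries; %s",
      trial, trait,
      if (length(checks)) "check-adjusted values returned"
      else "centered raw values returned"), call. = FALSE)
    out <- list(trial_id = trial, trait = trait,
                blues = blues[order(names(blues))],
                sigma2_G = NA_real_, MVD = NA_real_, h2 = NA_real_,
                n_lines = length(tab), note = "unestimable repeatability")
    class(out) <- "trial_summary"
    return(out)
  }

  d <- data.frame(line = factor(plots$line_id),
                  rep = factor(plots$replicate),
                  value = plots$value)
  has_rep <- nlevels(d$rep) > 1L
  fit <- if (has_rep)
    stats::lm(value ~ 0 + line + rep, data = d,
              contrasts = list(rep = "contr.sum"))
  else stats::lm(value ~ 0 + line, data = d)
  cn <- paste0("line", levels(d$line))
  blues <- stats::coef(fit)[cn]
  names(blues) <- levels(d$line)

  # suppressWarnings: summary.lm warns on (near-)noiseless data
  V <- suppressWarnings(stats::vcov(fit))[cn, cn, drop = FALSE]
  L <- length(blues)
  dv <- diag(V)
  # mean over all pairs i<j of Var(BLUE_i - BLUE_j)
  MVD <- ((L - 1) * sum(dv) - (sum(V) - sum(dv))) / (L * (L - 1) / 2)

  vc <- .reml_one_factor(d, has_rep)
  sigma2_G <- vc[["sigma2_G"]]
  h2 <- if (is.na(sigma2_G) || (sigma2_G + MVD / 2) <= 0) 0
        else clamp01(sigma2_G / (sigma2_G + MVD / 2))
  out <- list(trial_id = trial, trait = trait, blues = blues,
              sigma2_G = sigma2_G, sigma2_e = vc[["sigma2_e"]],
              MVD = MVD, h2 = h2,
              n_lines = L, note = NA_character_)
  class(out) <- "trial_summary"
  out
}

# REML genetic variance of the one-random-factor model, via lme4 with a
# method-of-moments fallback for degenerate (e.g. noiseless) data
.reml_one_factor <- function(d, has_rep) {
  form <- if (has_rep) value ~ rep + (1 | line) else value ~ (1 | line)
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(form, data = d, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             check.conv.grad = "ignore",
                                             check.conv.hess = "ignore")))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    vc <- lme4::VarCorr(fit)
    return(c(sigma2_G = as.numeric(vc$line),
             sigma2_e = attr(vc, "sc")^2))
  }
  # fallback: expected mean squares of the (near-)balanced ANOVA
  a <- stats::anova(stats::lm(
    if (has_rep) value ~ rep + line else value ~ line, data = d))
  msl <- a["line", "Mean Sq"]
  mse <- if ("Residuals" %in% rownames(a)) a["Residuals", "Mean Sq"] else 0
  if (is.na(mse)) mse <- 0
  r <- mean(table(d$line))
  c(sigma2_G = max((msl - mse) / r, 0), sigma2_e = mse)
}

#' @export
print.trial_summary <- function(x, ...) {
  cat(sprintf("Trial %s (%s): %d lines, sigma2_G = %s, MVD = %s, h2 = %s\n",
              x$trial_id, x$trait, x$n_lines,
              format(x$sigma2_G, digits = 4), format(x$MVD, digits = 4),
              format(x$h2, digits = 3)))
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Filter trials on repeatability
#'
#' Retains trials whose repeatability exceeds the threshold (strictly
#' larger than, default 0.3).  Trials with unestimable repeatability
#' (`h2` is `NA`, i.e. unreplicated preliminary yield trials) are retained
#' by default so that their check-adjusted values remain available to
#' genomics-assisted models.
#'
#' @param summaries list of [trial_blues()] results.
#' @param threshold repeatability threshold (default 0.3).
#' @param keep_unestimable keep trials with `NA` repeatability?
#' @return the retained subset of `summaries`.
#' @export
filter_trials <- function(summaries, threshold = 0.3, keep_unestimable = TRUE) {
  if (!length(summaries)) return(summaries)
  keep <- vapply(summaries, function(s) {
    if (is.na(s$h2)) keep_unestimable else s$h2 > threshold
  }, logical(1))
  summaries[keep]
}

#' Across-trial combination of stage-1 BLUEs
#'
#' Second stage of the phenotypic analysis: combines per-trial BLUEs with
#' the two-way model \eqn{y_{ij} = \mu + g_i + t_j + e_{ij}}, trial
#' effects always fixed.  Line effects are fitted as fixed to obtain
#' across-trial BLUEs and as random (iid, REML) to estimate the genetic
#' variance \eqn{\sigma^2_G}; the residual absorbs the trial-by-line
#' interaction.  Estimation uses all available cells (unbalanced least
#' squares); missing line-by-trial cells are allowed as long as the design
#' stays connected.
#'
#' Line BLUEs are reported on the grand-mean scale (trial effects sum to
#' zero); adding a constant to every record of one trial therefore shifts
#' all BLUEs by the same amount and leaves every line contrast, ranking
#' and downstream correlation unchanged.
#'
#' @param blues data frame of stage-1 BLUEs with columns `line_id`,
#'   `trial_id`, `value`.
#' @return list with elements `blues` (named per-line vector, on the
#'   grand-mean scale), `sigma2_G` (REML; `NA` for a single trial),
#'   `n_trials`.
#' @export
combine_trials <- function(blues) {
  req <- c("line_id", "trial_id", "value")
  miss <- setdiff(req, names(blues))
  if (length(miss))
    stop_selix("missing columns: ", paste(miss, collapse = ", "))
  trials <- unique(blues$trial_id)
  if (length(trials) == 1L) {
    v <- c(tapply(blues$value, blues$line_id, mean))
    return(list(blues = v[order(names(v))], sigma2_G = NA_real_,
                n_trials = 1L))
  }
  comp <- design_components(blues$line_id, blues$trial_id)
  if (length(comp) > 1L)
    stop_selix("disconnected line-by-trial design; trial groups: ",
               paste(vapply(comp, function(g) paste(g, collapse = "+"),
                            character(1)), collapse = " | "))
  d <- data.frame(line = factor(blues$line_id),
                  trial = factor(blues$trial_id),
                  value = blues$value)
  fit <- stats::lm(value ~ 0 + line + trial, data = d,
                   contrasts = list(trial = "contr.sum"))
  cn <- paste0("line", levels(d$line))
  bl <- stats::coef(fit)[cn]
  names(bl) <- levels(d$line)

  rfit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(value ~ trial + (1 | line), data = d, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             check.conv.grad = "ignore",
                                             check.conv.hess = "ignore")))),
    error = function(e) NULL)
  s2g <- if (is.null(rfit)) NA_real_ else as.numeric(lme4::VarCorr(rfit)$line)
  list(blues = bl, sigma2_G = s2g, n_trials = length(trials))
}

#' Write trial summaries to CSV
#'
#' One row per trial and trait: `trial_id, trait, n_lines, sigma2_G, MVD,
#' h2`, floating point at 8 significant digits.
#'
#' @param summaries list of [trial_blues()] results.
#' @param path output CSV path.
#' @export
write_trial_summaries <- function(summaries, path) {
  df <- do.call(rbind, lapply(summaries, function(s)
    data.frame(trial_id = s$trial_id, trait = s$trait, n_lines = s$n_lines,
               sigma2_G = signif(s$sigma2_G, 8), MVD = signif(s$MVD, 8),
               h2 = signif(s$h2, 8), stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
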