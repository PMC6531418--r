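#' Forward-prediction sampling scheme
#'
#' Defines the replicated training/validation resampling design: models
#' are trained on lines first tested in the training years and validated
#' against lines first tested in each validation year.  Per resample,
#' `n_train` lines are drawn (without replacement) from the training pool
#' and `n_valid` candidates from the validation-year cohort; the
#' preliminary-yield-trial set is identical with the validation
#' candidates.
#'
#' @param training_years integer vector of training years (`NULL`: taken
#'   from the dataset's configuration).
#' @param validation_years integer vector of validation years (`NULL`:
#'   from the dataset's configuration).
#' @param n_train training-population size per resample (default 300).
#' @param n_valid validation-candidate count per resample (default 100).
#' @param n_resamples number of resamples per validation year (default 30).
#' @param fractions selected fractions evaluated for the response to
#'   selection (default 10-50%).
#' @param combined_fraction total fraction for the combined two-index
#'   strategy (default 0.10, split 5% + 5%).
#' @param seed master seed; per-resample child seeds are drawn once from
#'   this seed, so any single resample is reproducible in isolation.
#' @return an object of class `forward_scheme`.
#' @export
forward_scheme <- function(training_years = NULL, validation_years = NULL,
                           n_train = 300L, n_valid = 100L,
                           n_resamples = 30L,
                           fractions = seq(0.1, 0.5, by = 0.1),
                           combined_fraction = 0.10, seed = 1L) {
  if (any(fractions <= 0 | fractions > 1))
    stop_selix("fractions must lie in (0, 1]")
  structure(list(training_years = training_years,
                 validation_years = validation_years,
                 n_train = as.integer(n_train), n_valid = as.integer(n_valid),
                 n_resamples = as.integer(n_resamples),
                 fractions = fractions,
                 combined_fraction = combined_fraction,
                 seed = as.integer(seed)),
            class = "forward_scheme")
}

.TRAITS <- c("GY", "PC", "PY")
.PREDICTORS <- c("GY", "PC", "PY",
                 "Index_GPD", "Index_GYD", "Index_HP", "Index_HY")

# index scores (named vector) for all four restriction indices given
# per-trait value lists and a beta source ("same" = values themselves)
.index_scores_from <- function(values, defs) {
  out <- list()
  roles <- index_roles()
  for (i in seq_len(nrow(roles))) {
    nm <- roles$index[i]
    def <- defs[[nm]]
    sc <- values[[roles$primary[i]]] - def$beta * values[[roles$secondary[i]]]
    out[[paste0("Index_", nm)]] <- sc
  }
  out
}

# restriction-index definitions from per-trait value vectors
.index_defs_from <- function(values, source) {
  roles <- index_roles()
  defs <- list()
  for (i in seq_len(nrow(roles))) {
    p <- roles$primary[i]; s <- roles$secondary[i]
    C <- cov2_matrix(stats::var(values[[p]]), stats::var(values[[s]]),
                     stats::cov(values[[p]], values[[s]]),
                     traits = c(p, s), source = source)
    defs[[roles$index[i]]] <- restriction_weights(C, name = roles$index[i])
  }
  defs
}

#' Run the replicated forward-prediction experiment
#'
#' Executes the full pipeline on a (typically simulated) breeding
#' programme: marker QC, imputation and kinship; two-stage phenotypic
#' analysis (per-trial BLUEs, repeatability filter at 0.3, across-trial
#' combination); then, for each validation year and resample, compares
#' three selection methods:
#' \describe{
#'   \item{phenotypic}{the candidates' own preliminary-yield-trial
#'     records (check-adjusted), index weights from the training lines'
#'     phenotypic variance-covariance matrix;}
#'   \item{genomics-based}{GBLUP trained on the sampled training lines'
#'     multi-environment BLUEs, candidates predicted through kinship,
#'     index weights from the genomic (GEBV) variance-covariance matrix;}
#'   \item{genomics-assisted}{weighted GBLUP additionally containing the
#'     candidates' own PYT records with a separate residual variance.}
#' }
#' For each of the seven predictors (three traits and four restriction
#' indices) the harness records heritability-corrected prediction
#' accuracies against all seven observed variables, and, per selected
#' fraction, the predicted selected mean and relative response to
#' selection for grain yield, protein content and protein yield, plus the
#' combined 5%+5% two-index strategies.  Index weights are always
#' estimated on the training population and applied unchanged to the
#' candidates; observed (validation) index values use the validation
#' population's phenotypic variance-covariance matrix.
#'
#' Cohorts are derived from the phenotype records: each line belongs to
#' the year of its first multi-environment testing; lines tested in
#' several years (check varieties) are excluded from training and
#' validation pools.
#'
#' @param dataset a [simulate_population()] result, or any list with
#'   elements `markers` (coded line x marker matrix) and `phenotypes`
#'   (long plot-level trait table).
#' @param scheme a [forward_scheme()].
#' @param h2_threshold repeatability threshold for the trial filter.
#' @param verbose print progress?
#' @return an object of class `forward_eval`: list with `results` (long
#'   data frame: method, predictor, response_trait, fraction, resample,
#'   validation_year, accuracy, h2_gen, mu_pop, mu_sel_hat,
#'   rel_response_pct), `summary` (means and standard deviations over
#'   resamples), `scheme`, and `n_lines_used`.
#' @export
run_forward_prediction <- function(dataset, scheme = forward_scheme(),
                                   h2_threshold = 0.3, verbose = FALSE) {
  if (!all(c("markers", "phenotypes") %in% names(dataset)))
    stop_selix("'dataset' needs elements markers and phenotypes")
  ph <- dataset$phenotypes

  # year roles
  tr_years <- scheme$training_years
  va_years <- scheme$validation_years
  if ((is.null(tr_years) || is.null(va_years)) && !is.null(dataset$config)) {
    yrs <- dataset$config$years
    if (is.null(tr_years)) tr_years <- yrs$year[yrs$role == "training"]
    if (is.null(va_years)) va_years <- yrs$year[yrs$role == "validation"]
  }
  if (is.null(tr_years) || is.null(va_years))
    stop_selix("training and validation years must be given (no config present)")

  # markers -> kinship
  mk <- impute_markers(qc_markers(dataset$markers))
  K <- compute_kinship(mk)

  # stage 1: per-trial BLUEs and repeatability
  met <- ph[ph$stage == "MET", , drop = FALSE]
  pyt <- ph[ph$stage == "PYT", , drop = FALSE]
  if (!nrow(met)) stop_selix("no MET records in phenotypes")
  summaries <- list()
  for (tr in unique(met$trial_id))
    for (t in .TRAITS) {
      d <- met[met$trial_id == tr & met$trait == t, , drop = FALSE]
      if (nrow(d)) summaries[[paste(tr, t)]] <- trial_blues(d)
    }
  retained <- filter_trials(summaries, threshold = h2_threshold)

  trial_year <- tapply(ph$year, ph$trial_id, function(x) x[1])
  stage1 <- do.call(rbind, lapply(retained, function(s)
    data.frame(line_id = names(s$blues), trial_id = s$trial_id,
               year = trial_year[[s$trial_id]], trait = s$trait,
               value = unname(s$blues), stringsAsFactors = FALSE)))

  # cohorts: year of first MET testing; multi-year lines are checks
  met_years <- tapply(met$year, met$line_id, function(x) sort(unique(x)))
  cohort <- vapply(met_years, `[`, numeric(1), 1L)
  checks <- names(met_years)[lengths(met_years) > 1L]

  # PYT check-adjusted values per trait (averaged over PYT trials)
  pyt_vals <- list()
  if (nrow(pyt)) {
    for (t in .TRAITS) {
      acc <- list()
      for (tr in unique(pyt$trial_id)) {
        d <- pyt[pyt$trial_id == tr & pyt$trait == t, , drop = FALSE]
        if (nrow(d)) acc[[tr]] <- suppressWarnings(trial_blues(d))$blues
      }
      all_ids <- unique(unlist(lapply(acc, names)))
      v <- vapply(all_ids, function(id)
        mean(unlist(lapply(acc, function(b) b[id])), na.rm = TRUE),
        numeric(1))
      pyt_vals[[t]] <- v
    }
  }

  # across-trial BLUEs: training pool and each validation year
  comb <- function(years, trait) {
    d <- stage1[stage1$year %in% years & stage1$trait == trait, , drop = FALSE]
    if (!nrow(d)) stop_selix("no retained trials for ", trait,
                             " in years ", paste(years, collapse = ","))
    combine_trials(d)$blues
  }
  train_blues <- lapply(stats::setNames(.TRAITS, .TRAITS),
                        function(t) comb(tr_years, t))
  valid_obs <- lapply(stats::setNames(va_years, va_years), function(yr)
    lapply(stats::setNames(.TRAITS, .TRAITS), function(t) comb(yr, t)))

  in_k <- rownames(K)
  have_all <- function(bl, ids)
    ids[vapply(ids, function(i) all(vapply(bl, function(b) i %in% names(b),
                                           logical(1))), logical(1))]
  train_pool <- setdiff(names(cohort)[cohort %in% tr_years], checks)
  train_pool <- intersect(intersect(train_pool, in_k),
                          have_all(train_blues, train_pool))
  valid_pool <- lapply(stats::setNames(va_years, va_years), function(yr) {
    p <- setdiff(names(cohort)[cohort == yr], checks)
    p <- intersect(intersect(p, in_k), have_all(valid_obs[[as.character(yr)]], p))
    if (length(pyt_vals))
      p <- have_all(pyt_vals, p)
    sort(p)
  })

  if (scheme$n_train > length(train_pool))
    stop_selix(sprintf("n_train = %d exceeds training pool size %d",
                       scheme$n_train, length(train_pool)))
  small <- vapply(valid_pool, length, integer(1)) < scheme$n_valid
  if (any(small))
    stop_selix("n_valid exceeds validation pool size for year(s) ",
               paste(names(valid_pool)[small], collapse = ", "))

  # deterministic per-resample child seeds
  seed_mat <- with_seed(scheme$seed,
    matrix(sample.int(.Machine$integer.max - 1L,
                      scheme$n_resamples * length(va_years)),
           scheme$n_resamples, length(va_years)))

  rows <- vector("list", scheme$n_resamples * length(va_years))
  ri <- 0L
  for (vyi in seq_along(va_years)) {
    vy <- va_years[vyi]
    vkey <- as.character(vy)
    for (r in seq_len(scheme$n_resamples)) {
      ri <- ri + 1L
      rows[[ri]] <- with_seed(seed_mat[r, vyi], {
        tr <- sort(sample(train_pool, scheme$n_train))
        va <- sort(sample(valid_pool[[vkey]], scheme$n_valid))
        .forward_one(K, train_blues, valid_obs[[vkey]], pyt_vals,
                     tr, va, scheme, vy, r)
      })
      if (verbose)
        message(sprintf("year %s resample %d/%d done", vkey, r,
                        scheme$n_resamples))
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  out <- list(results = results, summary = summarize_forward(results),
              scheme = scheme,
              n_lines_used = c(train_pool = length(train_pool),
                               vapply(valid_pool, length, integer(1))))
  class(out) <- "forward_eval"
  out
}

# one training x validation combination
.forward_one <- function(K, train_blues, obs_blues, pyt_vals,
                         tr, va, scheme, vy, resample) {
  kin_idx_va <- match(va, rownames(K))
  obs <- lapply(obs_blues, function(b) b[va])

  # observed index values: validation population, phenotypic C
  obs_defs <- .index_defs_from(obs, "phenotypic")
  obs_all <- c(obs, .index_scores_from(obs, obs_defs))

  # genomic heritability per observed variable (GBLUP on candidates only)
  eig_va <- eigen(unclass(K)[kin_idx_va, kin_idx_va], symmetric = TRUE)
  h2g <- vapply(obs_all, function(y) {
    rec <- data.frame(line_id = names(y), value = as.numeric(y),
                      group = "MET", stringsAsFactors = FALSE)
    fit <- .fit_gblup_eigen(rec, K, kin_idx_va, NULL, eig = eig_va)
    clamp01((stats::var(y) - fit$sigma2_e) / stats::var(y))
  }, numeric(1))

  preds <- list()

  # phenotypic: candidates' own PYT records; beta from training BLUEs
  if (length(pyt_vals)) {
    pv <- lapply(pyt_vals, function(v) v[va])
    tb <- lapply(train_blues, function(b) b[tr])
    defs <- .index_defs_from(tb, "phenotypic")
    preds$phenotypic <- c(pv, .index_scores_from(pv, defs))
  }

  # genomics-based: GBLUP on training BLUEs, one eigendecomposition
  kin_idx_tr <- match(tr, rownames(K))
  eig_tr <- eigen(unclass(K)[kin_idx_tr, kin_idx_tr], symmetric = TRUE)
  fits_gb <- lapply(train_blues, function(b) {
    rec <- data.frame(line_id = tr, value = as.numeric(b[tr]),
                      group = "MET", stringsAsFactors = FALSE)
    .fit_gblup_eigen(rec, K, kin_idx_tr, NULL, eig = eig_tr)
  })
  gb_tr <- lapply(fits_gb, function(f) f$gebv[tr])
  gb_va <- lapply(fits_gb, function(f) f$gebv[va])
  defs_gb <- .index_defs_from(gb_tr, "genomic")
  preds$genomics_based <- c(gb_va, .index_scores_from(gb_va, defs_gb))

  # genomics-assisted: weighted GBLUP with candidates' PYT records
  if (length(pyt_vals)) {
    fits_ga <- lapply(.TRAITS, function(t) {
      rec <- rbind(
        data.frame(line_id = tr, value = as.numeric(train_blues[[t]][tr]),
                   group = "MET", stringsAsFactors = FALSE),
        data.frame(line_id = va, value = as.numeric(pyt_vals[[t]][va]),
                   group = "PYT", stringsAsFactors = FALSE))
      fit_gblup(rec, K, trait = t)
    })
    names(fits_ga) <- .TRAITS
    ga_tr <- lapply(fits_ga, function(f) f$gebv[tr])
    ga_va <- lapply(fits_ga, function(f) f$gebv[va])
    defs_ga <- .index_defs_from(ga_tr, "genomic")
    preds$genomics_assisted <- c(ga_va, .index_scores_from(ga_va, defs_ga))
  }

  out <- list()
  for (m in names(preds)) {
    pr <- preds[[m]]
    # accuracies: every predictor against every observed variable
    for (p in .PREDICTORS) {
      r <- vapply(.PREDICTORS, function(q) {
        h2 <- h2g[[q]]
        if (h2 <= 0) return(NA_real_)
        max(-1, min(1, stats::cor(pr[[p]], obs_all[[q]]) / sqrt(h2)))
      }, numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        method = m, predictor = p, response_trait = .PREDICTORS,
        fraction = NA_real_, resample = resample, validation_year = vy,
        accuracy = unname(r), h2_gen = unname(h2g[.PREDICTORS]),
        mu_pop = NA_real_, mu_sel_hat = NA_real_,
        rel_response_pct = NA_real_, stringsAsFactors = FALSE)
    }
    # responses to selection per fraction
    for (p in .PREDICTORS)
      for (f in scheme$fractions)
        out[[length(out) + 1L]] <-
          .response_rows(m, p, select_top(pr[[p]], f), f, obs, h2g,
                         resample, vy)
    # combined two-index strategies (5% + 5%)
    fc <- scheme$combined_fraction
    out[[length(out) + 1L]] <- .response_rows(
      m, "Combined_GPD_GYD",
      combined_selection(pr$Index_GPD, pr$Index_GYD, fc), fc, obs, h2g,
      resample, vy)
    out[[length(out) + 1L]] <- .response_rows(
      m, "Combined_HP_HY",
      combined_selection(pr$Index_HP, pr$Index_HY, fc), fc, obs, h2g,
      resample, vy)
  }
  do.call(rbind, out)
}

.response_rows <- function(method, predictor, sel, fraction, obs, h2g,
                           resample, vy) {
  mu <- vapply(obs, mean, numeric(1))
  mu_sel <- vapply(obs, function(v) mean(v[sel]), numeric(1))
  mu_hat <- mapply(predict_selected_mean, mu, mu_sel, h2g[.TRAITS])
  data.frame(
    method = method, predictor = predictor, response_trait = .TRAITS,
    fraction = fraction, resample = resample, validation_year = vy,
    accuracy = NA_real_, h2_gen = unname(h2g[.TRAITS]),
    mu_pop = unname(mu), mu_sel_hat = unname(mu_hat),
    rel_response_pct = unname(relative_response(mu_hat, mu)),
    stringsAsFactors = FALSE)
}

#' Summarise forward-prediction results over resamples
#'
#' Means and standard deviations of accuracy and relative response per
#' (method, predictor, response trait, fraction) cell, pooled over
#' resamples and validation years.
#'
#' @param results the `results` data frame of [run_forward_prediction()]
#'   (or a `forward_eval` object).
#' @return data frame with columns `method`, `predictor`,
#'   `response_trait`, `fraction`, `n`, `mean_accuracy`, `sd_accuracy`,
#'   `mean_rel_response_pct`, `sd_rel_response_pct`.
#' @export
summarize_forward <- function(results) {
  if (inherits(results, "forward_eval")) results <- results$results
  key <- list(method = results$method, predictor = results$predictor,
              response_trait = results$response_trait,
              fraction = ifelse(is.na(results$fraction), -1, results$fraction))
  agg <- function(v, f) as.vector(tapply(v, key, f))
  # tapply returns cells with the first grouping factor varying fastest,
  # matching expand.grid over the sorted unique levels
  grid <- do.call(expand.grid, c(lapply(key, function(k) sort(unique(k))),
                                 list(KEEP.OUT.ATTRS = FALSE,
                                      stringsAsFactors = FALSE)))
  out <- data.frame(
    grid,
    n = as.vector(tapply(results$accuracy, key, length)),
    mean_accuracy = agg(results$accuracy, function(x) mean(x, na.rm = TRUE)),
    sd_accuracy = agg(results$accuracy, function(x) stats::sd(x, na.rm = TRUE)),
    mean_rel_response_pct =
      agg(results$rel_response_pct, function(x) mean(x, na.rm = TRUE)),
    sd_rel_response_pct =
      agg(results$rel_response_pct, function(x) stats::sd(x, na.rm = TRUE)),
    stringsAsFactors = FALSE)
  out <- out[!is.na(out$n), , drop = FALSE]
  out$fraction[out$fraction == -1] <- NA_real_
  rownames(out) <- NULL
  out
}

#' @export
print.forward_eval <- function(x, ...) {
  cat(sprintf("Forward-prediction evaluation: %d result rows, %d resamples\n",
              nrow(x$results), x$scheme$n_resamples))
  acc <- x$summary[is.na(x$summary$fraction) &
                     x$summary$predictor == x$summary$response_trait &
                     x$summary$predictor %in% .TRAITS, ]
  if (nrow(acc)) {
    cat("  mean accuracy (predictor = response):\n")
    for (i in seq_len(nrow(acc)))
      cat(sprintf("    %-18s %-3s %.3f\n", acc$method[i], acc$predictor[i],
                  acc$mean_accuracy[i]))
  }
  invisible(x)
}

#' Write forward-prediction results to CSV
#'
#' `eval_results.csv` holds the full per-resample table (8 significant
#' digits) and `eval_summary.csv` the per-cell means and standard
#' deviations (4 significant digits).
#'
#' @param x a [run_forward_prediction()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_eval_result <- function(x, dir) {
  if (!inherits(x, "forward_eval")) stop_selix("'x' must be a forward_eval")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  res <- x$results
  for (cl in c("accuracy", "h2_gen", "mu_pop", "mu_sel_hat",
               "rel_response_pct"))
    res[[cl]] <- signif(res[[cl]], 8)
  p1 <- file.path(dir, "eval_results.csv")
  utils::write.csv(res, p1, row.names = FALSE, quote = FALSE)
  smm <- x$summary
  for (cl in c("mean_accuracy", "sd_accuracy", "mean_rel_response_pct",
               "sd_rel_response_pct"))
    smm[[cl]] <- signif(smm[[cl]], 4)
  p2 <- file.path(dir, "eval_summary.csv")
  utils::write.csv(smm, p2, row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2))
}
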