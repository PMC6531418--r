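#' Configuration for the synthetic breeding programme
#'
#' Defines the population and trial structure used by
#' [simulate_population()]: a set of inbred line families genotyped at
#' biallelic SNPs, with additive bivariate genetic values for grain yield
#' (GY, dt/ha) and protein content (PC, %) showing a configurable
#' (typically strongly negative) genetic correlation, phenotyped in
#' replicated multi-environment trials (MET) and unreplicated preliminary
#' yield trials (PYT).
#'
#' Lines are split into single-year cohorts: each line is phenotyped in the
#' MET trials of its cohort year only, mirroring a breeding programme in
#' which every line is assigned to the year of its first testing.  Lines of
#' validation cohorts additionally receive one PYT plot in the year
#' preceding their MET year.  A small set of replicated check varieties is
#' grown in every trial, which connects the line-by-trial design across
#' years and provides the replication needed to adjust unreplicated PYT
#' records.
#'
#' @param n_lines number of breeding lines.
#' @param n_families number of bi-parental families; every line belongs to
#'   exactly one family (families are drawn at random, so realised family
#'   sizes vary, typically between 1 and ~15 progeny).
#' @param n_markers number of biallelic SNP markers (at least 10).
#' @param maf_range range of minor allele frequencies, within (0, 0.5].
#' @param genetic_corr_gy_pc target genetic correlation between grain
#'   yield and protein content, in [-1, 1].
#' @param trait_means named vector `c(GY=, PC=)` of population means
#'   (dt/ha and %).
#' @param genetic_sd named vector of genetic standard deviations per trait.
#' @param h2_met named vector of single-plot heritabilities in MET trials,
#'   each in (0, 1).
#' @param h2_pyt named vector of single-plot heritabilities in PYT trials,
#'   each in (0, 1).
#' @param trial_sd named vector of standard deviations of trial main
#'   effects per trait.
#' @param het_rate residual heterozygosity rate of the inbred lines
#'   (probability that a within-family segregating marker is scored 0).
#' @param n_checks number of replicated check lines grown in every trial.
#' @param years data frame with columns `year`, `n_trials`, `n_reps`,
#'   `role` (`"training"` or `"validation"`); one cohort per row.
#' @param seed integer seed; the same seed yields byte-identical output.
#'
#' @return an object of class `sim_config`.
#' @seealso [simulate_population()]
#' @export
sim_config <- function(n_lines = 900L,
                       n_families = 180L,
                       n_markers = 1000L,
                       maf_range = c(0.1, 0.5),
                       genetic_corr_gy_pc = -0.5,
                       trait_means = c(GY = 80, PC = 14),
                       genetic_sd = c(GY = 4, PC = 0.8),
                       h2_met = c(GY = 0.4, PC = 0.7),
                       h2_pyt = c(GY = 0.2, PC = 0.3),
                       trial_sd = c(GY = 5, PC = 0.5),
                       het_rate = 0.02,
                       n_checks = 5L,
                       years = default_years(),
                       seed = 1L) {
  traits <- c("GY", "PC")
  chk_trait_vec <- function(x, nm) {
    if (!all(traits %in% names(x)))
      stop_selix(sprintf("'%s' must be a named vector with elements GY and PC", nm))
    x[traits]
  }
  trait_means <- chk_trait_vec(trait_means, "trait_means")
  genetic_sd <- chk_trait_vec(genetic_sd, "genetic_sd")
  h2_met <- chk_trait_vec(h2_met, "h2_met")
  h2_pyt <- chk_trait_vec(h2_pyt, "h2_pyt")
  trial_sd <- chk_trait_vec(trial_sd, "trial_sd")
  if (any(c(h2_met, h2_pyt) <= 0) || any(c(h2_met, h2_pyt) >= 1))
    stop_selix("heritabilities (h2_met, h2_pyt) must lie strictly within (0, 1)")
  if (n_markers < 10L)
    stop_selix("n_markers must be at least 10")
  if (n_families > n_lines)
    stop_selix("n_families must not exceed n_lines")
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop_selix("maf_range must lie within (0, 0.5]")
  if (abs(genetic_corr_gy_pc) > 1)
    stop_selix("genetic_corr_gy_pc must lie in [-1, 1]")
  req <- c("year", "n_trials", "n_reps", "role")
  if (!is.data.frame(years) || !all(req %in% names(years)))
    stop_selix("'years' must be a data frame with columns year, n_trials, n_reps, role")
  if (!all(years$role %in% c("training", "validation")))
    stop_selix("year roles must be 'training' or 'validation'")
  structure(list(
    n_lines = as.integer(n_lines), n_families = as.integer(n_families),
    n_markers = as.integer(n_markers), maf_range = maf_range,
    genetic_corr_gy_pc = genetic_corr_gy_pc, trait_means = trait_means,
    genetic_sd = genetic_sd, h2_met = h2_met, h2_pyt = h2_pyt,
    trial_sd = trial_sd, het_rate = het_rate, n_checks = as.integer(n_checks),
    years = years, seed = as.integer(seed)), class = "sim_config")
}

#' Default multi-year trial structure
#'
#' Three training years followed by four validation years, each with three
#' replicated MET trials, emulating a line breeding programme in which
#' models are trained on earlier years and validated on cohorts first
#' tested in later years.
#'
#' @return data frame with columns `year`, `n_trials`, `n_reps`, `role`.
#' @export
default_years <- function() {
  data.frame(
    year = 2010:2016,
    n_trials = 3L,
    n_reps = 2L,
    role = c(rep("training", 3), rep("validation", 4)),
    stringsAsFactors = FALSE
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic breeding-programme configuration\n")
  cat(sprintf("  lines: %d in %d families, markers: %d (MAF %.2f-%.2f)\n",
              x$n_lines, x$n_families, x$n_markers,
              x$maf_range[1], x$maf_range[2]))
  cat(sprintf("  genetic correlation GY/PC: %.2f\n", x$genetic_corr_gy_pc))
  cat(sprintf("  plot h2 MET: GY %.2f, PC %.2f; PYT: GY %.2f, PC %.2f\n",
              x$h2_met["GY"], x$h2_met["PC"], x$h2_pyt["GY"], x$h2_pyt["PC"]))
  cat(sprintf("  years: %s\n",
              paste(sprintf("%d(%s)", x$years$year, substr(x$years$role, 1, 1)),
                    collapse = " ")))
  invisible(x)
}

#' Simulate a multi-year wheat breeding programme
#'
#' Generates a population of inbred lines in family groups with founder
#' haplotype mixing (so within-family kinship exceeds across-family
#' kinship), additive genetic values for grain yield and protein content
#' driven by bivariate-normal marker effects whose correlation induces the
#' configured genetic correlation, and plot-level phenotypes for MET and
#' PYT stages.  Protein yield is derived as \eqn{PY = GY \times PC / 100}
#' on every plot (dt/ha), never simulated independently.
#'
#' Phenotype model per plot: trait mean + trial effect + additive line
#' value + residual, with the residual variance set from the stage's
#' single-plot heritability, \eqn{\sigma^2_e = \sigma^2_G (1-h^2)/h^2}.
#' Trial-by-line interaction is folded into the plot residual.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `sim_dataset`: a list with elements
#'   \describe{
#'     \item{markers}{lines x markers matrix coded -1/0/1,}
#'     \item{true_bv}{data frame of per-line additive values (`bv_gy`,
#'       `bv_pc`, centered, in trait units) plus family and cohort year,}
#'     \item{phenotypes}{long plot-level trait table (`line_id`,
#'       `trial_id`, `year`, `stage`, `trait`, `replicate`, `value`),}
#'     \item{family_id}{named integer vector,}
#'     \item{check_lines}{ids of the replicated check lines,}
#'     \item{effects}{markers x 2 matrix of marker effects (GY, PC),}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' cfg <- sim_config(n_lines = 120, n_families = 30, n_markers = 200,
#'                   years = data.frame(year = 2010:2012, n_trials = 2,
#'                                      n_reps = 2,
#'                                      role = c("training", "training",
#'                                               "validation")))
#' sim <- simulate_population(cfg)
#' str(sim$phenotypes)
#' @export
simulate_population <- function(config) {
  if (!inherits(config, "sim_config"))
    stop_selix("'config' must be a sim_config object")
  with_seed(config$seed, {
    n <- config$n_lines
    m <- config$n_markers
    nf <- config$n_families
    line_id <- sprintf("L%04d", seq_len(n))
    marker_id <- sprintf("M%04d", seq_len(m))

    family <- sample.int(nf, n, replace = TRUE)
    names(family) <- line_id

    # population allele frequencies, MAF within the configured range
    p <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    flip <- stats::runif(m) < 0.5
    p[flip] <- 1 - p[flip]

    # two founder gametes per family; progeny inherit one allele per marker
    H1 <- matrix(stats::rbinom(nf * m, 1L, rep(p, each = nf)), nf, m)
    H2 <- matrix(stats::rbinom(nf * m, 1L, rep(p, each = nf)), nf, m)
    pick <- matrix(stats::runif(n * m) < 0.5, n, m)
    a <- ifelse(pick, H1[family, , drop = FALSE], H2[family, , drop = FALSE])
    Z <- 2 * a - 1
    seg <- H1[family, , drop = FALSE] != H2[family, , drop = FALSE]
    het <- seg & (matrix(stats::runif(n * m), n, m) < config$het_rate)
    Z[het] <- 0
    dimnames(Z) <- list(line_id, marker_id)
    storage.mode(Z) <- "integer"

    # correlated marker effects -> additive values, rescaled to the
    # configured genetic standard deviations
    rho <- config$genetic_corr_gy_pc
    Lc <- chol(matrix(c(1, rho, rho, 1), 2))
    eff <- matrix(stats::rnorm(m * 2), m, 2) %*% Lc
    colnames(eff) <- c("GY", "PC")
    rownames(eff) <- marker_id
    g <- Z %*% eff
    for (t in c("GY", "PC")) {
      s <- stats::sd(g[, t])
      if (s == 0) stop_selix("degenerate genotypes: zero genetic variance")
      g[, t] <- (g[, t] - mean(g[, t])) / s * config$genetic_sd[t]
    }

    checks <- line_id[seq_len(min(config$n_checks, n))]
    years <- config$years
    cohort <- sample(rep_len(years$year, n))
    names(cohort) <- line_id
    # checks are grown everywhere; give them the first training cohort
    cohort[checks] <- years$year[years$role == "training"][1]

    sd_e <- function(stage, trait) {
      h2 <- if (stage == "MET") config$h2_met[trait] else config$h2_pyt[trait]
      config$genetic_sd[trait] * sqrt((1 - h2) / h2)
    }

    recs <- list()
    add_plots <- function(ids, trial, year, stage, rep_no) {
      gy <- config$trait_means["GY"] + trial_eff["GY"] + g[ids, "GY"] +
        stats::rnorm(length(ids), 0, sd_e(stage, "GY"))
      pc <- config$trait_means["PC"] + trial_eff["PC"] + g[ids, "PC"] +
        stats::rnorm(length(ids), 0, sd_e(stage, "PC"))
      gy <- pmax(gy, 0)
      pc <- pmin(pmax(pc, 0.1), 99.9)
      py <- gy * pc / 100
      data.frame(
        line_id = rep(ids, 3L),
        trial_id = trial, year = year, stage = stage,
        trait = rep(c("GY", "PC", "PY"), each = length(ids)),
        replicate = rep_no,
        value = c(gy, pc, py),
        stringsAsFactors = FALSE
      )
    }

    for (yi in seq_len(nrow(years))) {
      yr <- years$year[yi]
      cohort_lines <- line_id[cohort == yr & !(line_id %in% checks)]
      for (tr in seq_len(years$n_trials[yi])) {
        trial <- sprintf("MET_%d_%d", yr, tr)
        trial_eff <- c(GY = stats::rnorm(1, 0, config$trial_sd["GY"]),
                       PC = stats::rnorm(1, 0, config$trial_sd["PC"]))
        ids <- c(cohort_lines, checks)
        for (rp in seq_len(years$n_reps[yi]))
          recs[[length(recs) + 1L]] <- add_plots(ids, trial, yr, "MET", rp)
      }
      if (years$role[yi] == "validation") {
        # single unreplicated PYT plot per candidate in the preceding year,
        # plus replicated checks
        trial <- sprintf("PYT_%d", yr - 1L)
        trial_eff <- c(GY = stats::rnorm(1, 0, config$trial_sd["GY"]),
                       PC = stats::rnorm(1, 0, config$trial_sd["PC"]))
        recs[[length(recs) + 1L]] <-
          add_plots(cohort_lines, trial, yr - 1L, "PYT", 1L)
        for (rp in 1:3)
          recs[[length(recs) + 1L]] <-
            add_plots(checks, trial, yr - 1L, "PYT", rp)
      }
    }
    phenotypes <- do.call(rbind, recs)
    rownames(phenotypes) <- NULL

    mu_py <- (config$trait_means["GY"] + g[, "GY"]) *
      (config$trait_means["PC"] + g[, "PC"]) / 100
    true_bv <- data.frame(
      line_id = line_id,
      family = unname(family),
      year = unname(cohort),
      bv_gy = unname(g[, "GY"]),
      bv_pc = unname(g[, "PC"]),
      bv_py = unname(mu_py - mean(mu_py)),
      stringsAsFactors = FALSE
    )

    structure(list(markers = Z, true_bv = true_bv, phenotypes = phenotypes,
                   family_id = family, check_lines = checks,
                   effects = eff, config = config),
              class = "sim_dataset")
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("Synthetic breeding programme: %d lines x %d markers, %d plot records\n",
              nrow(x$markers), ncol(x$markers), nrow(x$phenotypes)))
  cat(sprintf("  trials: %s\n",
              paste(utils::head(unique(x$phenotypes$trial_id), 6), collapse = ", ")))
  cat(sprintf("  realised cor(bv_gy, bv_pc) = %.3f\n",
              stats::cor(x$true_bv$bv_gy, x$true_bv$bv_pc)))
  invisible(x)
}
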