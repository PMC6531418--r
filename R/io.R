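#' Read and write the genotype TSV dialect
#'
#' Tab-separated, first column `line_id`, remaining columns one per
#' marker, cells coded `-1`, `0`, `1` or `NA` (line-major layout).
#'
#' @param markers lines x markers matrix.
#' @param path file path.
#' @return `read_genotypes()` returns the coded matrix with dimnames.
#' @export
write_genotypes <- function(markers, path) {
  .check_codes(markers)
  df <- data.frame(line_id = rownames(markers), markers,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE)
  if (names(df)[1] != "line_id")
    stop_selix("genotype TSV must start with a line_id column")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$line_id
  .check_codes(m)
  m
}

#' Read genotypes from a VCF file
#'
#' Maps GT fields of biallelic sites to line codes: `0/0` to -1, `0/1`
#' (or `1/0`) to 0, `1/1` to 1, missing to `NA`; phased separators are
#' accepted.  Multi-allelic sites are rejected.  Samples become lines and
#' variant ids become marker names.
#'
#' @param path path to an (uncompressed or gzipped) VCF file.
#' @return lines x markers coded matrix.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop_selix("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt)
  if (any(multi))
    stop_selix("multi-allelic sites are not supported: ",
               paste(utils::head(vcfR::getID(v)[multi], 5), collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  code[gt == "0/0"] <- -1L
  code[gt %in% c("0/1", "1/0")] <- 0L
  code[gt == "1/1"] <- 1L
  bad <- !is.na(gt) & gt != "./." & is.na(code)
  if (any(bad))
    stop_selix("unrecognised GT values: ",
               paste(utils::head(unique(gt[bad]), 5), collapse = ", "))
  t(code)
}

#' Read and write the long-format phenotype CSV
#'
#' Columns `line_id, trial_id, year, stage, trait, replicate, value`;
#' stages are `MET`/`PYT`, traits `GY`/`PC`/`PY`.  Wide layouts (one
#' column per trait) are rejected with a converting hint.
#'
#' @param phenotypes long-format data frame.
#' @param path file path.
#' @return `read_phenotypes()` returns the validated data frame.
#' @export
write_phenotypes <- function(phenotypes, path) {
  .check_phenotypes(phenotypes)
  ph <- phenotypes
  ph$value <- signif(ph$value, 8)
  utils::write.csv(ph, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_phenotypes(df)
  df
}

.check_phenotypes <- function(df) {
  req <- c("line_id", "trial_id", "year", "stage", "trait", "replicate",
           "value")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    wide <- intersect(c("GY", "PC", "PY"), names(df))
    if (length(wide))
      stop_selix("phenotype table looks wide (columns ",
                 paste(wide, collapse = ", "),
                 "); pivot to long format with columns ",
                 paste(req, collapse = ", "))
    stop_selix("missing phenotype columns: ", paste(miss, collapse = ", "))
  }
  if (!all(df$stage %in% c("MET", "PYT")))
    stop_selix("stage must be MET or PYT")
  if (!all(df$trait %in% c("GY", "PC", "PY")))
    stop_selix("trait must be GY, PC or PY")
  if (anyDuplicated(df[c("line_id", "trial_id", "trait", "replicate")]))
    stop_selix("duplicated (line_id, trial_id, trait, replicate) records")
  bad_pc <- df$trait == "PC" & (df$value <= 0 | df$value >= 100)
  if (any(bad_pc)) stop_selix("protein content must lie in (0, 100) %")
  if (any(df$value < 0 & df$trait %in% c("GY", "PY")))
    stop_selix("GY and PY must be non-negative")
  invisible(TRUE)
}

#' Read and write a kinship matrix as square TSV
#'
#' Header row and first column carry the line ids; entries are written
#' with 8 significant digits.
#'
#' @param K kinship matrix ([compute_kinship()]).
#' @param path file path.
#' @return `read_kinship()` returns the symmetric matrix.
#' @export
write_kinship <- function(K, path) {
  df <- data.frame(line_id = rownames(K),
                   signif(unclass(K), 8), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$line_id
  (m + t(m)) / 2
}

#' Write a simulated dataset to disk
#'
#' Writes `genotypes.tsv`, `phenotypes.csv` and `truth.csv` (per-line
#' true breeding values) into `dir`; refuses to overwrite existing files
#' unless `force = TRUE`.
#'
#' @param dataset a [simulate_population()] result.
#' @param dir output directory (created if missing).
#' @param force overwrite existing files?
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir, force = FALSE) {
  if (!inherits(dataset, "sim_dataset"))
    stop_selix("'dataset' must be a sim_dataset")
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
    message("created output directory ", dir)
  }
  paths <- file.path(dir, c("genotypes.tsv", "phenotypes.csv", "truth.csv"))
  exists <- file.exists(paths)
  if (any(exists) && !force)
    stop_selix("refusing to overwrite without force = TRUE: ",
               paste(paths[exists], collapse = ", "))
  write_genotypes(dataset$markers, paths[1])
  write_phenotypes(dataset$phenotypes, paths[2])
  tb <- dataset$true_bv
  for (cl in c("bv_gy", "bv_pc", "bv_py")) tb[[cl]] <- signif(tb[[cl]], 8)
  utils::write.csv(tb, paths[3], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Assemble or load a run configuration
#'
#' A run configuration binds all stages of the pipeline together: either
#' paths to genotype/phenotype files or a simulation block, a forward
#' scheme, marker-QC thresholds, and the master seed.
#' `read_run_config()` loads it from YAML.
#'
#' @param genotypes,phenotypes input paths (`NULL` when simulating).
#' @param sim list of [sim_config()] arguments (`NULL` when reading files).
#' @param scheme list of [forward_scheme()] arguments.
#' @param qc list with `call_rate`, `maf_min`, `max_missing`.
#' @param out_dir output directory for [run_pipeline()].
#' @param seed master seed applied to simulation and scheme unless they
#'   set their own.
#' @return an object of class `run_config`.
#' @export
run_config <- function(genotypes = NULL, phenotypes = NULL, sim = NULL,
                       scheme = list(), qc = list(), out_dir = "selix_run",
                       seed = 1L) {
  if (is.null(sim) && (is.null(genotypes) || is.null(phenotypes)))
    stop_selix("either a sim block or genotype and phenotype paths are required")
  qc_def <- list(call_rate = 0.90, maf_min = 0.05, max_missing = 0.10)
  qc <- utils::modifyList(qc_def, as.list(qc))
  structure(list(genotypes = genotypes, phenotypes = phenotypes,
                 sim = sim, scheme = as.list(scheme), qc = qc,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y[intersect(names(y),
                                  names(formals(run_config)))])
}

#' Run the full pipeline from a configuration
#'
#' Simulates (or loads) the dataset, runs the forward-prediction
#' experiment and writes `eval_results.csv`, `eval_summary.csv`, the
#' resolved configuration (`config_resolved.yaml`) and a run log into the
#' output directory.  Outputs are deterministic for a fixed
#' configuration.
#'
#' @param config a [run_config()] object (or path to a YAML file).
#' @return invisibly, the [run_forward_prediction()] result.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config"))
    stop_selix("'config' must be a run_config or a YAML path")
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)

  if (!is.null(config$sim)) {
    sim_args <- config$sim
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    if (!is.null(sim_args$years) && is.list(sim_args$years))
      sim_args$years <- as.data.frame(sim_args$years,
                                      stringsAsFactors = FALSE)
    dataset <- simulate_population(do.call(sim_config, sim_args))
  } else {
    dataset <- list(
      markers = read_genotypes(config$genotypes),
      phenotypes = read_phenotypes(config$phenotypes))
  }

  sch_args <- config$scheme
  if (is.null(sch_args$seed)) sch_args$seed <- config$seed
  scheme <- do.call(forward_scheme, sch_args)

  mk <- qc_markers(dataset$markers, call_rate = config$qc$call_rate,
                   maf_min = config$qc$maf_min,
                   max_missing = config$qc$max_missing)
  dataset$markers <- mk
  res <- run_forward_prediction(dataset, scheme)
  write_eval_result(res, config$out_dir)

  resolved <- unclass(config)
  resolved$scheme <- lapply(unclass(scheme), function(x) x)
  yaml::write_yaml(resolved, file.path(config$out_dir,
                                       "config_resolved.yaml"))
  log <- c(sprintf("selix %s on R %s",
                   as.character(utils::packageVersion("selix")),
                   paste(R.version$major, R.version$minor, sep = ".")),
           sprintf("seed: %d", config$seed),
           sprintf("qc: %s", attr(mk, "qc_report") |>
                     (\(r) paste(names(r), r, sep = "=", collapse = " "))()),
           sprintf("result rows: %d", nrow(res$results)))
  writeLines(log, file.path(config$out_dir, "run.log"))
  invisible(res)
}
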