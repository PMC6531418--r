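# internal helpers shared across modules

# run `code` under a fixed seed without clobbering the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_selix <- function(...) stop(..., call. = FALSE)

# connected components of the bipartite line x trial design,
# returned as a list of trial-id groups
design_components <- function(line_id, trial_id) {
  lines <- unique(line_id)
  trials <- unique(trial_id)
  comp <- seq_along(trials)
  names(comp) <- trials
  # iterate label propagation through shared lines until stable
  repeat {
    changed <- FALSE
    for (ln in lines) {
      tr <- unique(trial_id[line_id == ln])
      if (length(tr) > 1L) {
        lab <- min(comp[tr])
        if (any(comp[tr] != lab)) {
          comp[tr] <- lab
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  split(trials, comp)
}
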