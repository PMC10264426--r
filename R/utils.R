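# Seed management: operations that take an explicit seed run under their own
# RNG stream and restore the caller's stream afterwards, so seeded calls are
# reproducible without clobbering the session RNG.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Deterministic fan-out of one global seed into per-stage seeds (kept < 2^31).
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(offset) * 7919L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_same_shape <- function(a, b) {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (!identical(da, db))
    stop("shape mismatch: ", paste(da, collapse = "x"), " vs ",
         paste(db, collapse = "x"))
}
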