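# Internal seeding helpers.  All stochastic operations take an explicit
# integer seed; nested components derive child seeds by a fixed counter
# scheme so results do not depend on evaluation order, and the caller's
# global RNG state is restored afterwards.

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seed from a master seed and up to three counters.
# Plain modular hash; stays inside 32-bit integer range.
child_seed <- function(master, a, b = 0L, c = 0L) {
  s <- (abs(as.double(master)) %% 97003) * 20011 +
    as.double(a) * 7907 + as.double(b) * 211 + as.double(c) * 7 + 13
  as.integer(s %% 2147483629)
}

check_labels <- function(labels, n = NULL) {
  labels <- as_cohort_labels(labels)
  if (!is.null(n) && length(labels) != n)
    stop("labels length (", length(labels), ") does not match table rows (",
         n, ")")
  labels
}
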