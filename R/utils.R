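# internal helpers shared across modules

# Deterministic sub-seed derivation. R's RNG seed must stay below 2^31, so
# mix in double precision and reduce modulo a Mersenne prime.
.mix_seed <- function(seed, k) {
  s <- (abs(as.double(seed)) %% 2147483647) * 69069 + as.double(k) * 30011 + 1
  as.integer(s %% 2147483629L) + 1L
}

# Run `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so package functions never clobber it.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

.assert <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

# population standard deviation (denominator n)
.sd_pop <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

# format numbers for TSV output with >= 10 significant digits, byte-stable
.fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "NA" else format(v, digits = 12, scientific = FALSE, trim = TRUE)
  }, character(1))
}
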