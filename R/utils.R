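# Internal helpers shared across the package.

# Classed error so callers (and the CLI) can distinguish validation failures
# (user/data problems) from numerical failures (optimizer problems).
stop_nk <- function(msg, class = "neurokin_validation_error", ...) {
  stop(errorCondition(msg, ..., class = c(class, "neurokin_error")))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

assert_scalar_number <- function(x, name) {
  if (!is_scalar_number(x)) {
    stop_nk(sprintf("'%s' must be a single finite number", name))
  }
  invisible(x)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state on exit.
# Keeps all package randomness explicit: no simulation leaks into or depends
# on the global stream.
with_preserved_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic per-subject substream seed derived from the study seed.
# Uses a 31-bit linear hash so derived seeds stay valid R integers.
derive_seed <- function(seed, index, salt = 0L) {
  m <- 2147483647 # 2^31 - 1
  s <- (as.double(seed) %% m)
  s <- (s * 48271 + as.double(index) * 16807 + as.double(salt) * 69621) %% m
  as.integer(s) + 1L
}

# Composite trapezoid rule over an irregular grid; returns the cumulative
# integral at every grid point (0 at the first).
trapz_cumulative <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  dx <- diff(x)
  mid <- (y[-n] + y[-1L]) / 2
  c(0, cumsum(dx * mid))
}

# All permutations of seq_len(n), as a matrix with one permutation per row.
# Used for the exact Spearman permutation test (n <= 8 => at most 40320 rows).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out[[k]] <- cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
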