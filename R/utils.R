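# Internal helpers shared across modules.

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
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
  }
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Wilson score interval for a binomial proportion.
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0L) {
    return(c(estimate = NA_real_, lower = NA_real_, upper = NA_real_))
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(estimate = p, lower = max(0, centre - half), upper = min(1, centre + half))
}

# Normal-theory t interval for a mean.
t_ci <- function(values, conf = 0.95) {
  values <- values[is.finite(values)]
  n <- length(values)
  m <- mean(values)
  if (n < 2L) {
    return(c(estimate = m, lower = NA_real_, upper = NA_real_))
  }
  half <- stats::qt(1 - (1 - conf) / 2, df = n - 1) * stats::sd(values) / sqrt(n)
  c(estimate = m, lower = m - half, upper = m + half)
}

stop_input <- function(...) stop(..., call. = FALSE)

# Fast grouped mean over a character key; returns named vector.
grouped_mean <- function(x, key) {
  s <- rowsum(x, key, na.rm = TRUE)
  n <- rowsum(as.numeric(!is.na(x)), key)
  out <- as.vector(s) / as.vector(n)
  out[as.vector(n) == 0] <- NA_real_
  names(out) <- rownames(s)
  out
}
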