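# Internal helpers shared across modules.

# Run code with a temporary RNG state seeded from `seed`; restores the caller's
# RNG so simulations never perturb user code. `seed = NULL` leaves RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Round half away from zero
#'
#' Base R's `round()` uses banker's rounding; printed mass-error tables round
#' half-up, so 1.15 ppm prints as 1.2. Used when reproducing published
#' delta-ppm values.
#'
#' @param x Numeric vector (non-negative in the ppm use case).
#' @param digits Decimal places (default 1).
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# Lexicographically minimal rotation of a character vector; canonical form for
# directed cycles (no reflection: peptide rings are directional).
canonical_rotation <- function(x) {
  n <- length(x)
  if (n <= 1L) return(x)
  rots <- vapply(seq_len(n), function(i) {
    paste(x[c(i:n, seq_len(i - 1L))], collapse = "\r")
  }, character(1))
  best <- which.min(rank(rots, ties.method = "min"))
  x[c(best:n, seq_len(best - 1L))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
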