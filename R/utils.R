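# internal numeric helpers shared across modules

# harmonic number a_n = sum_{i=1}^{n} 1/i
harmonic <- function(n) {
  if (n < 1) return(0)
  sum(1 / seq_len(n))
}

# sum_{i=1}^{n} 1/i^2
harmonic2 <- function(n) {
  if (n < 1) return(0)
  sum(1 / seq_len(n)^2)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)

# seed the session RNG when a seed is supplied; callers that pass NULL
# inherit the ambient RNG state (so set.seed() outside works as usual)
seed_rng <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
      stop_domain("'seed' must be a single integer")
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

assert_square_dist <- function(D, what = "distance matrix") {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop_domain(what, " must be square")
  if (max(abs(D - t(D))) > 1e-8) stop_domain(what, " must be symmetric")
  if (any(abs(diag(D)) > 1e-8)) stop_domain(what, " must have a zero diagonal")
  D
}
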