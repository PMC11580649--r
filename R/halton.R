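#' Halton low-discrepancy sequence
#'
#' Radical-inverse sequence in a prime base, the quasi-random number stream
#' used for simulated maximum likelihood. Element `i` is obtained by writing
#' `i` in base `base` and mirroring its digits about the radix point, so the
#' sequence fills (0, 1) far more evenly than pseudo-random draws. The first
#' `discard` elements (which cluster near simple fractions) can be skipped,
#' as is conventional before transforming to normal draws.
#'
#' @param base prime base (2, 3, 5, ...).
#' @param n number of points.
#' @param discard number of initial points to skip (default 0).
#' @return Numeric vector of `n` values strictly inside (0, 1).
#' @examples
#' halton_sequence(2, 4)  # 1/2 1/4 3/4 1/8
#' @export
halton_sequence <- function(base, n, discard = 0) {
  if (!.is_prime(base)) stop("'base' must be a prime number")
  if (n < 1) stop("'n' must be >= 1")
  i <- (discard + 1):(discard + n)
  x <- numeric(n)
  f <- 1 / base
  while (any(i > 0)) {
    x <- x + f * (i %% base)
    i <- i %/% base
    f <- f / base
  }
  x
}

#' Halton draw plan for simulated likelihood
#'
#' Fixes every quasi-random ingredient of a mixed-logit fit: one prime base
#' per random coefficient (assigned in column order starting at 2), the
#' number of draws, and how many leading points are discarded. Two fits with
#' the same plan see bit-identical draws, so estimation is deterministic.
#'
#' @param n_random number of random coefficients.
#' @param n_draws draws per respondent (study default 1000).
#' @param discard leading Halton points to skip (default 10).
#' @param primes optional explicit prime bases (distinct, one per dimension).
#' @return Object of class `halton_plan`.
#' @export
halton_plan <- function(n_random, n_draws = 1000, discard = 10, primes = NULL) {
  if (n_random < 1) stop("'n_random' must be >= 1")
  if (n_draws < 1) stop("'n_draws' must be >= 1")
  if (is.null(primes)) primes <- .primes(n_random)
  if (length(primes) != n_random || anyDuplicated(primes) ||
      !all(vapply(primes, .is_prime, logical(1))))
    stop("'primes' must be distinct primes, one per random coefficient")
  if (n_draws < 50)
    warning("fewer than 50 draws: simulation noise may dominate")
  structure(list(primes = as.integer(primes), n_draws = as.integer(n_draws),
                 discard = as.integer(discard)),
            class = "halton_plan")
}

#' @export
print.halton_plan <- function(x, ...) {
  cat("Halton plan:", x$n_draws, "draws,", length(x$primes),
      "dimensions (primes", paste(x$primes, collapse = " "),
      "), discard", x$discard, "\n")
  invisible(x)
}

# standard-normal Halton draw matrix, one row per random coefficient
.halton_normal <- function(plan) {
  Z <- matrix(0, length(plan$primes), plan$n_draws)
  for (k in seq_along(plan$primes))
    Z[k, ] <- stats::qnorm(halton_sequence(plan$primes[k], plan$n_draws,
                                           plan$discard))
  Z  # n_random x n_draws
}
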