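# internal numerical helpers

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# row-wise log-sum-exp; S must be a numeric matrix
.row_logsumexp <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  m + log(rowSums(exp(S - m)))
}

# row-wise log-mean-exp (used for averaging simulated likelihood over draws)
.row_logmeanexp <- function(S) {
  .row_logsumexp(S) - log(ncol(S))
}

.is_prime <- function(n) {
  if (length(n) != 1L || is.na(n) || n != floor(n) || n < 2) return(FALSE)
  if (n < 4) return(TRUE)
  if (n %% 2 == 0) return(FALSE)
  d <- 3
  while (d * d <= n) {
    if (n %% d == 0) return(FALSE)
    d <- d + 2
  }
  TRUE
}

# first k primes
.primes <- function(k) {
  out <- integer(0)
  n <- 2L
  while (length(out) < k) {
    if (.is_prime(n)) out <- c(out, n)
    n <- n + 1L
  }
  out
}

.stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.01, "***", ifelse(p < 0.05, "**", ifelse(p < 0.10, "*", ""))))
}
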