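# Panel random-parameters (mixed) logit by simulated maximum likelihood.
#
# Random coefficients are normal, beta_r = mu + sigma * z_r, with z_r built
# from Halton sequences (one prime base per coefficient). The same draw
# matrix is shared by all respondents; the panel product over a respondent's
# tasks sits inside the draw average, so the simulated likelihood is
#   L_n = (1/R) sum_r prod_t P_nt(beta_r).
# All heavy work is dense matrix algebra over an N x R utility matrix.

.rpl_setup <- function(data, random, plan, optout_asc) {
  if (is.na(data$J))
    stop("mixed logit requires the same number of alternatives in every task")
  Xf <- .model_matrix(data, optout_asc)
  cols <- colnames(data$X)
  if (is.null(random)) random <- cols
  ridx <- match(random, colnames(Xf))
  if (anyNA(ridx)) stop("unknown random column(s): ",
                        paste(random[is.na(ridx)], collapse = ", "))
  fidx <- setdiff(seq_len(ncol(Xf)), ridx)
  if (length(plan$primes) != length(ridx))
    stop("plan has ", length(plan$primes), " dimensions for ",
         length(ridx), " random coefficients")
  jc <- which(data$chosen) - (data$task[data$chosen] - 1L) * data$J
  list(Xf = Xf, ridx = ridx, fidx = fidx, Z = .halton_normal(plan),
       J = data$J, Tn = data$n_tasks, R = plan$n_draws, jc = jc,
       resp_of_row = data$resp_of_task[data$task],
       Y = as.numeric(data$chosen))
}

# simulated log-likelihood (and analytic gradient) at (mu, sg_raw, bfix)
.rpl_eval <- function(data, mu, sg, bfix, st, want_grad = FALSE) {
  J <- st$J; Tn <- st$Tn; R <- st$R
  B <- st$Z * sg + mu                     # n_random x R
  U <- st$Xf[, st$ridx, drop = FALSE] %*% B
  if (length(st$fidx))
    U <- U + drop(st$Xf[, st$fidx, drop = FALSE] %*% bfix)
  dim(U) <- c(J, Tn * R)
  m <- Reduce(pmax, lapply(seq_len(J), function(j) U[j, ]))
  U <- U - rep(m, each = J)
  E <- exp(U)
  denom <- .colSums(E, J, Tn * R)
  cols <- seq_len(Tn * R)
  lp <- U[(cols - 1L) * J + rep(st$jc, times = R)] - log(denom)
  S <- rowsum(matrix(lp, Tn, R), data$resp_of_task)   # n_resp x R
  a <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  l_n <- a + log(rowMeans(exp(S - a)))
  ll <- sum(l_n)
  if (!want_grad) return(list(loglik = ll))

  W <- exp(S - (l_n + log(R)))            # posterior draw weights per resp
  P <- E * rep(1 / denom, each = J)
  dim(P) <- c(J * Tn, R)
  D <- (st$Y - P) * W[st$resp_of_row, , drop = FALSE]
  G <- crossprod(st$Xf, D)                # K_total x R
  Gr <- G[st$ridx, , drop = FALSE]
  list(loglik = ll,
       grad_mu = rowSums(Gr),
       grad_sg = rowSums(Gr * st$Z),
       grad_fix = if (length(st$fidx)) rowSums(G[st$fidx, , drop = FALSE])
                  else numeric(0))
}

#' Simulated panel mixed-logit log-likelihood
#'
#' Evaluates the simulated log-likelihood of a panel random-parameters logit
#' at given means and spreads: per respondent, choice probabilities are
#' multiplied over that respondent's tasks within each Halton draw, averaged
#' over draws, and logged (guarded by log-sum-exp).
#'
#' @param data a balanced [choice_data()] object.
#' @param mu means of the random coefficients (one per random column).
#' @param sigma spreads (standard deviations) of the random coefficients.
#' @param fixed values of the non-random coefficients (the opt-out constant,
#'   plus any coded columns excluded from `random`), in model-matrix order.
#' @param plan a [halton_plan()] with one prime per random coefficient.
#' @param random character vector of random coded columns (default: all).
#' @param optout_asc include an opt-out constant (default `TRUE`).
#' @return The simulated log-likelihood (scalar).
#' @export
simulated_loglik <- function(data, mu, sigma, fixed = numeric(0), plan,
                             random = NULL, optout_asc = TRUE) {
  stopifnot(inherits(data, "choice_data"), inherits(plan, "halton_plan"))
  if (optout_asc && !any(data$optout > 0)) optout_asc <- FALSE
  st <- .rpl_setup(data, random, plan, optout_asc)
  if (length(fixed) != length(st$fidx))
    stop("'fixed' must have length ", length(st$fidx))
  .rpl_eval(data, mu, sigma, fixed, st)$loglik
}

#' Fit a panel random-parameters (mixed) logit model
#'
#' Simulated maximum likelihood for a panel mixed logit with independent
#' normally distributed coefficients on the effects-coded attribute columns
#' and a fixed opt-out constant. Halton draws (default 1000 per respondent,
#' first 10 points discarded, primes assigned in column order) make the fit
#' deterministic: no pseudo-random numbers are consumed. Starts from the
#' conditional-logit estimates with all spreads at 0.1; spreads are reported
#' as absolute values (the likelihood is symmetric in their sign). The
#' returned log-likelihood never falls below the conditional logit's, since
#' the zero-spread parameter point is retained as a fallback candidate.
#'
#' @param data a balanced [choice_data()] object.
#' @param n_draws Halton draws per respondent (study default 1000).
#' @param discard leading Halton points to skip (default 10).
#' @param random coded columns given random coefficients (default: all).
#' @param optout_asc include a fixed opt-out constant (default `TRUE`).
#' @param start optional list with elements `mu`, `sigma`, `fixed`.
#' @param maxit BFGS iteration cap.
#' @param hessian compute standard errors from the numerical Hessian
#'   (default `TRUE`; the costliest step for large draw counts).
#' @return Object of classes `rpl_fit`, `dce_fit` with elements `mu`,
#'   `sigma`, `fixed`, `loglik`, `aic`, `se`, `plan`, `converged`.
#' @export
fit_rpl <- function(data, n_draws = 1000, discard = 10, random = NULL,
                    optout_asc = TRUE, start = NULL, maxit = 400,
                    hessian = TRUE) {
  stopifnot(inherits(data, "choice_data"))
  if (optout_asc && !any(data$optout > 0)) optout_asc <- FALSE
  if (is.null(random)) random <- colnames(data$X)
  plan <- halton_plan(length(random), n_draws, discard)
  st <- .rpl_setup(data, random, plan, optout_asc)
  nr <- length(st$ridx); nf <- length(st$fidx)

  mnl <- fit_mnl(data, optout_asc = optout_asc)
  b_mnl <- stats::coef(mnl)
  if (is.null(start))
    start <- list(mu = b_mnl[st$ridx], sigma = rep(0.1, nr),
                  fixed = if (nf) b_mnl[st$fidx] else numeric(0))

  unpack <- function(p) list(mu = p[seq_len(nr)],
                             sg = p[nr + seq_len(nr)],
                             fx = if (nf) p[2 * nr + seq_len(nf)] else numeric(0))
  cache <- new.env(parent = emptyenv())
  evalp <- function(p) {
    if (!is.null(cache$p) && identical(cache$p, p)) return(cache$v)
    u <- unpack(p)
    v <- .rpl_eval(data, u$mu, u$sg, u$fx, st, want_grad = TRUE)
    cache$p <- p; cache$v <- v
    v
  }
  fn <- function(p) -evalp(p)$loglik
  gr <- function(p) { v <- evalp(p); -c(v$grad_mu, v$grad_sg, v$grad_fix) }

  p0 <- c(start$mu, start$sigma, start$fixed)
  opt <- stats::optim(p0, fn, gr, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-10))
  par <- opt$par
  ll <- -opt$value
  converged <- opt$convergence == 0

  # nesting guarantee: the degenerate sigma = 0 point reproduces the MNL
  p_mnl <- c(b_mnl[st$ridx], rep(0, nr), if (nf) b_mnl[st$fidx])
  if (mnl$loglik > ll + 1e-9) {
    par <- p_mnl
    ll <- .rpl_eval(data, par[seq_len(nr)], par[nr + seq_len(nr)],
                    if (nf) par[2 * nr + seq_len(nf)] else numeric(0),
                    st)$loglik
    converged <- FALSE
  }

  u <- unpack(par)
  sg_raw <- u$sg
  u$sg <- abs(u$sg)
  names(u$mu) <- random
  names(u$sg) <- random
  if (nf) names(u$fx) <- colnames(st$Xf)[st$fidx]
  coefs <- c(stats::setNames(u$mu, paste0("mu:", random)),
             stats::setNames(u$sg, paste0("sd:", random)),
             if (nf) stats::setNames(u$fx, colnames(st$Xf)[st$fidx]))

  se <- rep(NA_real_, length(coefs))
  V <- NULL
  if (hessian) {
    H <- tryCatch(stats::optimHess(par, fn, gr), error = function(e) NULL)
    if (!is.null(H)) {
      V <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(V)) se <- sqrt(pmax(diag(V), 0))
    }
  }
  names(se) <- names(coefs)

  K <- length(coefs)
  structure(list(coefficients = coefs,
                 mu = u$mu, sigma = u$sg, sigma_raw = sg_raw,
                 fixed = if (nf) u$fx else numeric(0),
                 random = random,
                 plan = plan,
                 loglik = ll,
                 n_par = K,
                 aic = 2 * K - 2 * ll,
                 se = se,
                 vcov = V,
                 converged = converged,
                 n_resp = data$n_resp,
                 n_tasks = data$n_tasks,
                 optout_asc = optout_asc,
                 space = data$space,
                 model = "RPL",
                 call = match.call()),
            class = c("rpl_fit", "dce_fit"))
}
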