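# Latent-class conditional logit with covariate-driven class membership.
#
# Respondent n belongs to class c with multinomial-logit probability
# pi_c(z_n) built from an intercept and binary covariates (last class is
# the reference with utility 0). Conditional on class, choices follow a
# class-specific conditional logit. Estimation is EM (posterior E-step;
# weighted-logit M-steps) from multiple perturbed starts, followed by a
# quasi-Newton polish of the full mixture likelihood.

#' Class-membership probabilities
#'
#' Multinomial logit over latent classes: class `c < C` has utility
#' `theta[c, ] %*% c(1, z)`; the last class is the reference with utility 0.
#'
#' @param covariates matrix (or data frame) of respondent covariates with
#'   one row per respondent, or a single covariate vector; may have zero
#'   columns for an intercept-only model.
#' @param theta matrix with `C - 1` rows and `1 + ncol(covariates)` columns
#'   (intercept first). A vector is taken as the single row of a 2-class
#'   model.
#' @return Matrix of membership probabilities (rows sum to 1) with `C`
#'   columns.
#' @export
membership_probabilities <- function(covariates, theta) {
  if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1)
  if (is.null(covariates)) covariates <- matrix(0, 1, 0)
  if (is.null(dim(covariates))) covariates <- matrix(covariates, nrow = 1)
  covariates <- as.matrix(covariates)
  if (ncol(theta) != 1 + ncol(covariates))
    stop("theta needs ", 1 + ncol(covariates), " columns (intercept first)")
  U <- cbind(1, covariates) %*% t(theta)      # n x (C-1)
  U <- cbind(U, 0)
  m <- U[cbind(seq_len(nrow(U)), max.col(U, ties.method = "first"))]
  E <- exp(U - m)
  E / rowSums(E)
}

# per-respondent per-class panel log-likelihoods and mixture pieces
.lca_parts <- function(data, class_betas, theta, optout_asc = TRUE) {
  C <- ncol(class_betas)
  lpS <- matrix(0, data$n_resp, C)
  for (c in seq_len(C)) {
    ev <- .mnl_eval(data, class_betas[, c], optout_asc)
    lpS[, c] <- drop(rowsum(ev$lp_task, data$resp_of_task))
  }
  cov <- data$covariates
  if (is.null(cov)) cov <- matrix(0, data$n_resp, 0)
  pi_n <- membership_probabilities(cov, theta)
  A <- lpS + log(pmax(pi_n, 1e-300))
  l_n <- .row_logsumexp(A)
  post <- exp(A - l_n)
  list(loglik = sum(l_n), posterior = post, prior = pi_n, lpS = lpS,
       l_n = l_n)
}

#' Latent-class mixture log-likelihood
#'
#' The panel mixture log-likelihood
#' `sum_n log sum_c pi_c(z_n) prod_t P_ntc(chosen)`, with the per-class
#' panel products computed in log space and combined by log-sum-exp.
#'
#' @param data a [choice_data()] object.
#' @param class_betas matrix of per-class coefficient vectors (coded columns
#'   plus opt-out constant), one column per class.
#' @param theta membership coefficient matrix, see
#'   [membership_probabilities()].
#' @param optout_asc does `class_betas` include an opt-out constant row?
#' @return Log-likelihood (scalar).
#' @export
lca_loglik <- function(data, class_betas, theta, optout_asc = TRUE) {
  stopifnot(inherits(data, "choice_data"))
  if (optout_asc && !any(data$optout > 0)) optout_asc <- FALSE
  .lca_parts(data, class_betas, theta, optout_asc)$loglik
}

# weighted multinomial-logit update of theta given posteriors w (n x C)
.fit_membership <- function(covariates, w, theta0) {
  C <- ncol(w)
  if (C < 2) return(theta0)
  Zint <- cbind(1, covariates)
  p <- ncol(Zint)
  fn <- function(v) {
    th <- matrix(v, C - 1, p)
    pi_n <- membership_probabilities(covariates, th)
    -sum(w * log(pmax(pi_n, 1e-300)))
  }
  gr <- function(v) {
    th <- matrix(v, C - 1, p)
    pi_n <- membership_probabilities(covariates, th)
    G <- t(w[, -C, drop = FALSE] - pi_n[, -C, drop = FALSE]) %*% Zint
    -as.vector(G)
  }
  # box constraints keep quasi-separated membership coefficients finite
  opt <- stats::optim(pmin(pmax(as.vector(theta0), -10), 10), fn, gr,
                      method = "L-BFGS-B", lower = -10, upper = 10,
                      control = list(maxit = 200, factr = 1e4))
  matrix(opt$par, C - 1, p)
}

# one EM pass returning updated parameters and the new log-likelihood
.lca_em <- function(data, class_betas, theta, optout_asc, max_iter, tol) {
  cov <- data$covariates
  if (is.null(cov)) cov <- matrix(0, data$n_resp, 0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    parts <- .lca_parts(data, class_betas, theta, optout_asc)
    w <- parts$posterior
    # M-step: class-specific weighted conditional logits (warm-started;
    # plain BFGS is enough, the final polish handles precision)
    for (c in seq_len(ncol(class_betas))) {
      wt <- w[, c][data$resp_of_task]
      opt <- stats::optim(class_betas[, c],
                          function(b) -.mnl_eval(data, b, optout_asc,
                                                 task_weights = wt)$loglik,
                          function(b) -.mnl_eval(data, b, optout_asc,
                                                 task_weights = wt)$gradient,
                          method = "BFGS",
                          control = list(maxit = 60, reltol = 1e-10))
      class_betas[, c] <- opt$par
    }
    theta <- .fit_membership(cov, w, theta)
    ll <- .lca_parts(data, class_betas, theta, optout_asc)$loglik
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(class_betas = class_betas, theta = theta, loglik = ll_old, iter = it)
}

#' Fit a latent-class conditional logit model
#'
#' Finite-mixture conditional logit with `n_classes` preference classes and
#' a covariate-driven multinomial-logit membership model (intercept plus one
#' coefficient per binary covariate for each non-reference class).
#' Estimation runs short EM from `n_starts` randomly perturbed starts around
#' the conditional-logit solution, continues the best start to EM
#' convergence (relative log-likelihood change below `tol`), then polishes
#' the full likelihood with BFGS using the analytic mixture gradient.
#' Classes are relabelled in descending order of their average posterior
#' share, so output order is deterministic.
#'
#' @param data a [choice_data()] object (covariates optional; without them
#'   the membership model is intercept-only).
#' @param n_classes number of latent classes (1 reduces to [fit_mnl()]).
#' @param n_starts random starts (default 20).
#' @param seed RNG seed for the start perturbations.
#' @param optout_asc include a per-class opt-out constant (default `TRUE`).
#' @param max_em EM iteration cap per start continuation (default 500).
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param aic_n denominator convention for the reported `aic_per_n`:
#'   `"choice_tasks"` (default) or `"respondents"`.
#' @param hessian compute standard errors from the numerical Hessian.
#' @return Object of classes `lca_fit`, `dce_fit` with per-class
#'   coefficients, membership `theta`, average posterior `class_shares`,
#'   log-likelihood, AIC and AIC/N.
#' @export
fit_lca <- function(data, n_classes = 2, n_starts = 20, seed = 1,
                    optout_asc = TRUE, max_em = 500, tol = 1e-8,
                    aic_n = c("choice_tasks", "respondents"),
                    hessian = TRUE) {
  stopifnot(inherits(data, "choice_data"))
  aic_n <- match.arg(aic_n)
  if (optout_asc && !any(data$optout > 0)) optout_asc <- FALSE
  C <- as.integer(n_classes)
  if (C < 1) stop("'n_classes' must be >= 1")

  mnl <- fit_mnl(data, optout_asc = optout_asc)
  Kf <- length(stats::coef(mnl))
  cov <- data$covariates
  if (is.null(cov)) cov <- matrix(0, data$n_resp, 0)
  p <- ncol(cov) + 1L

  if (C == 1L) {
    cb <- matrix(stats::coef(mnl), ncol = 1,
                 dimnames = list(names(stats::coef(mnl)), "class1"))
    fit <- structure(list(n_classes = 1L, class_betas = cb,
                          theta = matrix(numeric(0), 0, p),
                          class_shares = 1,
                          coefficients = stats::setNames(drop(cb),
                                                         rownames(cb)),
                          loglik = mnl$loglik, n_par = Kf,
                          aic = mnl$aic,
                          aic_per_n = mnl$aic / switch(aic_n,
                            choice_tasks = data$n_tasks,
                            respondents = data$n_resp),
                          aic_n_convention = aic_n,
                          se = mnl$se, vcov = mnl$vcov,
                          converged = mnl$converged, n_starts_used = 0L,
                          n_resp = data$n_resp, n_tasks = data$n_tasks,
                          covariate_names = colnames(data$covariates),
                          optout_asc = optout_asc, space = data$space,
                          model = "LCA", call = match.call()),
                     class = c("lca_fit", "dce_fit"))
    return(fit)
  }

  b0 <- stats::coef(mnl)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  starts <- lapply(seq_len(n_starts), function(s) {
    list(betas = b0 + matrix(stats::rnorm(Kf * C, sd = 0.5), Kf, C),
         theta = matrix(stats::rnorm((C - 1) * p, sd = 0.2), C - 1, p))
  })

  # short EM per start, then run the best to convergence
  short <- lapply(starts, function(s)
    .lca_em(data, s$betas, s$theta, optout_asc, max_iter = 15, tol = 1e-6))
  best <- short[[which.max(vapply(short, `[[`, 0, "loglik"))]]
  res <- .lca_em(data, best$class_betas, best$theta, optout_asc,
                 max_iter = max_em, tol = tol)

  # quasi-Newton polish of the full mixture likelihood
  pack <- function(cb, th) c(as.vector(cb), as.vector(th))
  unpack <- function(v) list(cb = matrix(v[seq_len(Kf * C)], Kf, C),
                             th = matrix(v[-seq_len(Kf * C)], C - 1, p))
  Zint <- cbind(1, cov)
  fn <- function(v) {
    u <- unpack(v)
    -.lca_parts(data, u$cb, u$th, optout_asc)$loglik
  }
  gr <- function(v) {
    u <- unpack(v)
    parts <- .lca_parts(data, u$cb, u$th, optout_asc)
    w <- parts$posterior
    gb <- matrix(0, Kf, C)
    for (c in seq_len(C)) {
      wt <- w[, c][data$resp_of_task]
      gb[, c] <- .mnl_eval(data, u$cb[, c], optout_asc,
                           task_weights = wt)$gradient
    }
    gt <- t(w[, -C, drop = FALSE] - parts$prior[, -C, drop = FALSE]) %*% Zint
    -c(as.vector(gb), as.vector(gt))
  }
  v0 <- pack(res$class_betas, res$theta)
  # bounded quasi-Newton: membership coefficients capped at +/-10 to keep
  # quasi-separated cells finite
  lo <- c(rep(-25, Kf * C), rep(-10, (C - 1) * p))
  hi <- -lo
  hi[seq_len(Kf * C)] <- 25
  opt <- stats::optim(pmin(pmax(v0, lo), hi), fn, gr, method = "L-BFGS-B",
                      lower = lo, upper = hi,
                      control = list(maxit = 300, factr = 1e3))
  v <- if (-opt$value >= res$loglik) opt$par else v0
  u <- unpack(v)
  ll <- .lca_parts(data, u$cb, u$th, optout_asc)$loglik

  # canonical label order: descending average posterior share
  parts <- .lca_parts(data, u$cb, u$th, optout_asc)
  shares <- colMeans(parts$posterior)
  o <- order(shares, decreasing = TRUE)
  cb <- u$cb[, o, drop = FALSE]
  Tfull <- rbind(u$th, 0)[o, , drop = FALSE]
  th <- sweep(Tfull, 2, Tfull[C, ])[-C, , drop = FALSE]
  parts <- .lca_parts(data, cb, th, optout_asc)
  shares <- colMeans(parts$posterior)

  if (any(shares < 0.01))
    warning("degenerate class: share below 1%")

  cn <- paste0("class", seq_len(C))
  dimnames(cb) <- list(names(b0), cn)
  dimnames(th) <- list(cn[-C], c("(intercept)",
                                 if (ncol(cov)) colnames(cov)))
  K <- Kf * C + (C - 1) * p
  coefs <- c(stats::setNames(as.vector(cb),
                             as.vector(outer(rownames(cb), cn,
                                             function(a, b) paste0(b, ":", a)))),
             stats::setNames(as.vector(t(th)),
                             as.vector(t(outer(rownames(th), colnames(th),
                                               function(a, b) paste0("theta:", a, ":", b))))))

  se <- rep(NA_real_, K)
  V <- NULL
  if (hessian) {
    vC <- c(as.vector(cb), as.vector(th))
    H <- tryCatch(stats::optimHess(vC, fn, gr), error = function(e) NULL)
    if (!is.null(H)) {
      V <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(V)) se <- sqrt(pmax(diag(V), 0))
    }
  }
  names(se) <- names(coefs)

  structure(list(n_classes = C,
                 class_betas = cb,
                 theta = th,
                 class_shares = shares,
                 coefficients = coefs,
                 loglik = ll,
                 n_par = K,
                 aic = 2 * K - 2 * ll,
                 aic_per_n = (2 * K - 2 * ll) / switch(aic_n,
                   choice_tasks = data$n_tasks,
                   respondents = data$n_resp),
                 aic_n_convention = aic_n,
                 se = se,
                 vcov = V,
                 converged = opt$convergence == 0,
                 n_starts_used = n_starts,
                 n_resp = data$n_resp,
                 n_tasks = data$n_tasks,
                 covariate_names = colnames(data$covariates),
                 optout_asc = optout_asc,
                 space = data$space,
                 model = "LCA",
                 call = match.call()),
            class = c("lca_fit", "dce_fit"))
}

#' Posterior class membership and aggregate shares
#'
#' Bayes posterior probability that each respondent belongs to each latent
#' class, combining the covariate-based membership prior with the
#' respondent's observed choice likelihood under each class. Aggregate
#' shares are the posterior column means.
#'
#' @param fit an `lca_fit` from [fit_lca()].
#' @param data the [choice_data()] the model was fitted to (or compatible
#'   new data).
#' @return List with `posterior` (matrix, rows sum to 1) and `shares`
#'   (named vector summing to 1).
#' @export
class_posteriors <- function(fit, data) {
  stopifnot(inherits(fit, "lca_fit"), inherits(data, "choice_data"))
  if (fit$n_classes == 1L)
    return(list(posterior = matrix(1, data$n_resp, 1,
                                   dimnames = list(NULL, "class1")),
                shares = c(class1 = 1)))
  parts <- .lca_parts(data, fit$class_betas, fit$theta, fit$optout_asc)
  post <- parts$posterior
  colnames(post) <- colnames(fit$class_betas)
  list(posterior = post,
       shares = stats::setNames(colMeans(post), colnames(post)))
}
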