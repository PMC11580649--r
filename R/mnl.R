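#' Logit choice probabilities
#'
#' Softmax of a utility vector with max-subtraction for numerical stability:
#' the probability of alternative `j` is `exp(V_j) / sum(exp(V))`. Adding a
#' constant to all utilities leaves the probabilities unchanged.
#'
#' @param utilities finite numeric vector of alternative utilities.
#' @return Probability vector of the same length, summing to 1.
#' @export
choice_probabilities <- function(utilities) {
  if (length(utilities) == 0) stop("empty choice set")
  if (any(!is.finite(utilities))) stop("utilities must be finite")
  e <- exp(utilities - max(utilities))
  e / sum(e)
}

# per-task max of a row-level vector (rows grouped contiguously by task)
.task_max <- function(u, data) {
  if (!is.na(data$J)) {
    U <- matrix(u, nrow = data$J)
    Reduce(pmax, lapply(seq_len(data$J), function(j) U[j, ]))
  } else {
    as.numeric(vapply(split(u, data$task), max, numeric(1)))
  }
}

# conditional-logit log-likelihood, analytic gradient and row probabilities.
# task_weights: optional per-task weights (latent-class M-step).
.mnl_eval <- function(data, beta, optout_asc = TRUE, task_weights = NULL) {
  Xf <- .model_matrix(data, optout_asc)
  if (length(beta) != ncol(Xf))
    stop("beta has length ", length(beta), "; expected ", ncol(Xf))
  u <- drop(Xf %*% beta)
  m <- .task_max(u, data)
  e <- exp(u - m[data$task])
  denom <- drop(rowsum(e, data$task))
  lp_task <- u[data$chosen] - m - log(denom)
  P <- e / denom[data$task]
  resid <- (as.numeric(data$chosen) - P)
  if (!is.null(task_weights)) {
    ll <- sum(task_weights * lp_task)
    resid <- resid * task_weights[data$task]
  } else {
    ll <- sum(lp_task)
  }
  list(loglik = ll, gradient = drop(crossprod(Xf, resid)),
       prob = P, lp_task = lp_task)
}

#' Conditional logit log-likelihood and analytic gradient
#'
#' The panel-pooled conditional (multinomial) logit log-likelihood
#' `sum over tasks of log P(chosen alternative)` and its analytic score
#' `sum of (x_chosen - sum_j P_j x_j)`, both evaluated at `beta`.
#'
#' @param data a [choice_data()] object.
#' @param beta coefficient vector: one entry per coded column, plus the
#'   opt-out alternative-specific constant if `optout_asc` is `TRUE`.
#' @param optout_asc include an opt-out constant as the final coefficient?
#' @return List with elements `loglik` (scalar) and `gradient` (vector).
#' @export
mnl_loglik_grad <- function(data, beta, optout_asc = TRUE) {
  stopifnot(inherits(data, "choice_data"))
  ev <- .mnl_eval(data, beta, optout_asc)
  list(loglik = ev$loglik, gradient = ev$gradient)
}

# columns with no within-task variation are inestimable
.dead_columns <- function(data, Xf) {
  sizes <- tabulate(data$task, nbins = data$n_tasks)
  S1 <- rowsum(Xf, data$task)
  S2 <- rowsum(Xf^2, data$task)
  wss <- colSums(S2 - S1^2 / sizes)
  colnames(Xf)[wss < 1e-10]
}

# quasi-Newton maximization with Newton polish to a gradient tolerance
.maximize <- function(par, fn, gr, gtol = 1e-6, maxit = 1000) {
  negfn <- function(p) -fn(p)
  neggr <- function(p) -gr(p)
  opt <- stats::optim(par, negfn, neggr, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12))
  par <- opt$par
  H <- NULL
  for (it in seq_len(20)) {
    g <- gr(par)
    if (max(abs(g)) < gtol) break
    H <- tryCatch(stats::optimHess(par, negfn, neggr), error = function(e) NULL)
    if (is.null(H)) break
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    ll0 <- fn(par)
    alpha <- 1
    repeat {
      cand <- par + alpha * step
      if (fn(cand) >= ll0 - 1e-12) { par <- cand; break }
      alpha <- alpha / 2
      if (alpha < 1e-6) break
    }
    if (alpha < 1e-6) break
  }
  g <- gr(par)
  list(par = par, loglik = fn(par), grad_norm = max(abs(g)),
       converged = max(abs(g)) < gtol)
}

#' Fit a conditional (multinomial) logit model
#'
#' Maximum-likelihood conditional logit for panel choice data: the baseline
#' model that the random-parameters and latent-class models generalize.
#' Starts from the zero vector (the likelihood is globally concave) and
#' polishes with Newton steps to a small gradient norm. The opt-out
#' alternative, when present, is captured by an alternative-specific
#' constant; designed (unlabelled) alternatives carry none.
#'
#' @param data a [choice_data()] object.
#' @param optout_asc include an opt-out alternative-specific constant
#'   (default `TRUE`).
#' @param cluster_se also compute respondent-clustered robust standard
#'   errors (stored as `se_cluster`).
#' @param start optional starting coefficient vector.
#' @param gtol gradient infinity-norm convergence tolerance.
#' @return Object of classes `mnl_fit`, `dce_fit` with coefficients,
#'   standard errors, log-likelihood, AIC and convergence information.
#' @export
fit_mnl <- function(data, optout_asc = TRUE, cluster_se = FALSE,
                    start = NULL, gtol = 1e-6) {
  stopifnot(inherits(data, "choice_data"))
  if (data$n_tasks < 1) stop("no choice tasks")
  if (optout_asc && !any(data$optout > 0)) optout_asc <- FALSE
  Xf <- .model_matrix(data, optout_asc)
  dead <- .dead_columns(data, Xf)
  if (length(dead) == ncol(Xf))
    stop("no identification: no coefficient varies within any choice task")
  if (length(dead))
    stop("no identification for column(s): ", paste(dead, collapse = ", "),
         " (constant within every choice task)")

  if (is.null(start)) start <- numeric(ncol(Xf))
  fn <- function(b) .mnl_eval(data, b, optout_asc)$loglik
  gr <- function(b) .mnl_eval(data, b, optout_asc)$gradient
  res <- .maximize(start, fn, gr, gtol = gtol)
  beta <- res$par
  names(beta) <- colnames(Xf)

  # perfect separation: every chosen probability driven to 1 (or runaway
  # coefficients heading there)
  ev_opt <- .mnl_eval(data, beta, optout_asc)
  separable <- all(ev_opt$lp_task > -1e-6) || any(abs(beta) > 15)
  if (separable)
    warning("data appear perfectly separable: coefficients diverge")

  H <- tryCatch(stats::optimHess(beta, function(b) -fn(b), function(b) -gr(b)),
                error = function(e) NULL)
  V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  se <- if (!is.null(V)) sqrt(pmax(diag(V), 0)) else rep(NA_real_, length(beta))
  names(se) <- names(beta)

  se_cluster <- NULL
  if (cluster_se && !is.null(V)) {
    ev <- .mnl_eval(data, beta, optout_asc)
    resid <- as.numeric(data$chosen) - ev$prob
    Srow <- Xf * resid
    Sresp <- rowsum(Srow, data$resp_of_task[data$task])
    meat <- crossprod(Sresp)
    Vc <- V %*% meat %*% V
    se_cluster <- sqrt(pmax(diag(Vc), 0))
    names(se_cluster) <- names(beta)
  }

  K <- length(beta)
  fit <- structure(list(coefficients = beta,
                        loglik = res$loglik,
                        n_par = K,
                        aic = 2 * K - 2 * res$loglik,
                        se = se,
                        se_cluster = se_cluster,
                        vcov = V,
                        converged = res$converged && !separable,
                        separable = separable,
                        grad_norm = res$grad_norm,
                        n_resp = data$n_resp,
                        n_tasks = data$n_tasks,
                        optout_asc = optout_asc,
                        space = data$space,
                        model = "MNL",
                        call = match.call()),
                   class = c("mnl_fit", "dce_fit"))
  fit
}
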