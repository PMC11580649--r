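# Shared fixtures and independent brute-force oracles. The oracles use
# plain loops and direct formula evaluation, deliberately sharing no code
# with the package's vectorized implementations.

tiny_space <- function() {
  attribute_space(list(a = c("a1", "a2", "a3"), b = c("b1", "b2")))
}

# independent long-format simulator for small fixtures (loops + sample())
make_tiny_data <- function(space, beta, n_resp = 30, n_tasks = 4, J = 2,
                           optout = TRUE, asc = -1, seed = 42,
                           covariates = NULL) {
  set.seed(seed)
  cand <- enumerate_candidates(space)
  rows <- vector("list", n_resp * n_tasks)
  i <- 0L
  cov <- NULL
  if (!is.null(covariates))
    cov <- matrix(rbinom(n_resp * length(covariates), 1, 0.5),
                  n_resp, length(covariates),
                  dimnames = list(NULL, covariates))
  for (r in seq_len(n_resp)) {
    for (t in seq_len(n_tasks)) {
      idx <- sample(nrow(cand), J)
      prof <- cand[idx, , drop = FALSE]
      X <- effects_code(space, prof)
      v <- drop(X %*% beta)
      if (optout) v <- c(v, asc)
      p <- exp(v) / sum(exp(v))
      ch <- sample(length(v), 1, prob = p)
      df <- data.frame(resp_id = sprintf("r%03d", r), task_id = t,
                       alt_id = c(as.character(seq_len(J)),
                                  if (optout) "optout"),
                       opt_out = c(rep(0L, J), if (optout) 1L),
                       choice = 0L, stringsAsFactors = FALSE)
      df$choice[ch] <- 1L
      prof2 <- prof
      if (optout) prof2 <- rbind(prof, NA)
      df <- cbind(df, prof2)
      if (!is.null(cov))
        df <- cbind(df, cov[rep(r, nrow(df)), , drop = FALSE])
      i <- i + 1L
      rows[[i]] <- df
    }
  }
  choice_data(do.call(rbind, rows), space, covariates = covariates)
}

# direct per-task conditional-logit log-likelihood
oracle_mnl_loglik <- function(data, beta, optout_asc = TRUE) {
  Xf <- if (optout_asc) cbind(data$X, data$optout) else data$X
  ll <- 0
  for (t in seq_len(data$n_tasks)) {
    rows <- which(data$task == t)
    v <- drop(Xf[rows, , drop = FALSE] %*% beta)
    p <- exp(v) / sum(exp(v))
    ll <- ll + log(p[data$chosen[rows]])
  }
  ll
}

# direct simulated panel likelihood: explicit triple loop over respondents,
# draws and tasks
oracle_simulated_loglik <- function(data, mu, sigma, asc, Z) {
  ll <- 0
  for (n in seq_len(data$n_resp)) {
    tasks <- which(data$resp_of_task == n)
    Ln <- 0
    for (r in seq_len(ncol(Z))) {
      b <- mu + sigma * Z[, r]
      pr <- 1
      for (t in tasks) {
        rows <- which(data$task == t)
        v <- drop(data$X[rows, , drop = FALSE] %*% b) +
          asc * data$optout[rows]
        p <- exp(v) / sum(exp(v))
        pr <- pr * p[data$chosen[rows]]
      }
      Ln <- Ln + pr
    }
    ll <- ll + log(Ln / ncol(Z))
  }
  ll
}

# direct latent-class mixture likelihood (explicit membership logit)
oracle_lca_loglik <- function(data, class_betas, theta, optout_asc = TRUE) {
  cov <- data$covariates
  if (is.null(cov)) cov <- matrix(0, data$n_resp, 0)
  C <- ncol(class_betas)
  Xf <- if (optout_asc) cbind(data$X, data$optout) else data$X
  ll <- 0
  for (n in seq_len(data$n_resp)) {
    eta <- drop(theta %*% c(1, cov[n, ]))
    pi_n <- exp(c(eta, 0)) / sum(exp(c(eta, 0)))
    tasks <- which(data$resp_of_task == n)
    mix <- 0
    for (c in seq_len(C)) {
      pr <- 1
      for (t in tasks) {
        rows <- which(data$task == t)
        v <- drop(Xf[rows, , drop = FALSE] %*% class_betas[, c])
        p <- exp(v) / sum(exp(v))
        pr <- pr * p[data$chosen[rows]]
      }
      mix <- mix + pi_n[c] * pr
    }
    ll <- ll + log(mix)
  }
  ll
}

# direct D-error: assemble the averaged information matrix set by set
oracle_d_error <- function(design, priors, include_optout = FALSE) {
  space <- design$space
  X <- effects_code(space,
                    design$profiles[, names(space$attributes), drop = FALSE])
  S <- design$n_sets
  J <- design$n_alts
  K <- space$n_columns
  I <- matrix(0, K, K)
  for (s in seq_len(S)) {
    Xs <- X[(s - 1) * J + seq_len(J), , drop = FALSE]
    if (include_optout) Xs <- rbind(Xs, 0)
    v <- drop(Xs %*% priors)
    p <- exp(v) / sum(exp(v))
    xbar <- colSums(Xs * p)
    for (j in seq_len(nrow(Xs)))
      I <- I + p[j] * tcrossprod(Xs[j, ] - xbar) / S
  }
  det(solve(I))^(1 / K)
}

# the published two-class level coefficients, copied as printed (class 1
# accuracy-driven, class 2 cost-driven); used as oracle inputs
published_class_levels <- function() {
  list(
    cost = cbind(c(0.70, -0.11, -0.59), c(2.48, -0.90, -1.58)),
    speed = cbind(c(-0.10, 0.23, -0.14), c(-0.11, 0.15, -0.05)),
    accuracy = cbind(c(-1.00, -0.06, -0.03, 1.09),
                     c(-0.36, -0.39, -0.11, 0.86)),
    anonymity = cbind(c(0.02, -0.20, 0.18), c(0.38, -0.37, -0.02)),
    app_type = cbind(c(0.17, -0.17), c(0.02, -0.02)),
    services = cbind(c(-0.04, -0.38, 0.10, 0.32),
                     c(-0.23, -0.04, -0.11, 0.38))
  )
}
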