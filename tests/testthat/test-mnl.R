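test_that("softmax probabilities behave like a logit kernel", {
  expect_equal(choice_probabilities(c(0, 0, 0)), rep(1/3, 3))
  u <- c(0.3, -1.2, 2.0)
  expect_equal(choice_probabilities(u + 5), choice_probabilities(u))
  expect_equal(sum(choice_probabilities(rnorm(6))), 1)
  # two alternatives one utility unit apart: logistic(1)
  expect_equal(choice_probabilities(c(1, 0)),
               c(0.7311, 0.2689), tolerance = 1e-4)
  # large utilities do not overflow
  expect_equal(choice_probabilities(c(1000, 1000)), c(0.5, 0.5))
  expect_error(choice_probabilities(numeric(0)), "empty")
})

test_that("log-likelihood equals -T log J at beta = 0 and matches the oracle", {
  dat <- make_tiny_data(tiny_space(), beta = c(0.6, -0.3, 0.4),
                        n_resp = 15, n_tasks = 3, seed = 5)
  K <- ncol(dat$X) + 1
  ll0 <- mnl_loglik_grad(dat, numeric(K))$loglik
  expect_equal(ll0, -dat$n_tasks * log(3))   # 2 designed + opt-out
  set.seed(8)
  for (i in 1:5) {
    b <- rnorm(K, sd = 0.7)
    expect_equal(mnl_loglik_grad(dat, b)$loglik, oracle_mnl_loglik(dat, b),
                 tolerance = 1e-10)
  }
})

test_that("analytic gradient matches central finite differences", {
  set.seed(314)
  dat <- make_tiny_data(tiny_space(), beta = c(0.5, -0.4, 0.8),
                        n_resp = 10, n_tasks = 5, seed = 314)  # 50 tasks
  K <- ncol(dat$X) + 1
  beta <- rnorm(K, sd = 0.5)
  g <- mnl_loglik_grad(dat, beta)$gradient
  h <- 1e-6
  g_fd <- vapply(seq_len(K), function(j) {
    e <- numeric(K); e[j] <- h
    (mnl_loglik_grad(dat, beta + e)$loglik -
       mnl_loglik_grad(dat, beta - e)$loglik) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(g - g_fd) / pmax(abs(g_fd), 1)), 1e-6)
})

test_that("ML fit recovers simulated coefficients and dominates beta = 0", {
  truth <- c(0.8, -0.5, 0.6)
  dat <- make_tiny_data(tiny_space(), beta = truth, n_resp = 500,
                        n_tasks = 6, asc = -1.5, seed = 99)
  fit <- fit_mnl(dat)
  expect_true(fit$converged)
  expect_lt(fit$grad_norm, 1e-5)
  est <- coef(fit)
  full_truth <- c(truth, -1.5)
  expect_true(all(abs(est - full_truth) < 3 * fit$se))
  expect_gt(fit$loglik, mnl_loglik_grad(dat, numeric(4))$loglik)
  expect_equal(fit$aic, 2 * 4 - 2 * fit$loglik)
})

test_that("unidentified data (identical coding within every task) errors", {
  sp <- tiny_space()
  prof <- data.frame(a = "a1", b = "b1")
  df <- do.call(rbind, lapply(1:8, function(t)
    data.frame(resp_id = "r1", task_id = t, alt_id = 1:2,
               choice = c(1, 0), a = prof$a, b = prof$b)))
  dat <- choice_data(df, sp)
  expect_error(fit_mnl(dat, optout_asc = FALSE), "identification")
})

test_that("separable data is flagged rather than raised", {
  sp <- attribute_space(list(x = c("hi", "lo")))
  df <- do.call(rbind, lapply(1:12, function(t)
    data.frame(resp_id = paste0("r", t), task_id = 1, alt_id = 1:2,
               choice = c(1, 0), x = c("hi", "lo"))))
  dat <- choice_data(df, sp)
  expect_warning(fit <- fit_mnl(dat, optout_asc = FALSE), "separable")
  expect_false(fit$converged)
})

test_that("two-alternative MNL equals logistic regression on differences", {
  sp <- attribute_space(list(x = c("hi", "lo")))
  set.seed(21)
  dat <- make_tiny_data(sp, beta = 0.9, n_resp = 120, n_tasks = 4, J = 2,
                        optout = FALSE, seed = 21)
  fit <- fit_mnl(dat, optout_asc = FALSE)
  # independent route: glm on the coded difference of each pair
  first <- seq(1, nrow(dat$X), by = 2)
  dx <- dat$X[first, 1] - dat$X[first + 1, 1]
  y <- as.integer(dat$chosen[first])
  keep <- dx != 0
  glm_fit <- suppressWarnings(
    glm(y[keep] ~ 0 + dx[keep], family = binomial()))
  expect_equal(unname(coef(fit)), unname(coef(glm_fit)), tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(logLik(glm_fit)) +
                 sum(!keep) * log(1/2), tolerance = 1e-8)
})

test_that("the likelihood is concave: multistart reaches one optimum", {
  dat <- make_tiny_data(tiny_space(), beta = c(0.4, -0.2, 0.3),
                        n_resp = 40, n_tasks = 4, seed = 77)
  f0 <- fit_mnl(dat)
  set.seed(123)
  for (i in 1:3) {
    fi <- fit_mnl(dat, start = rnorm(4, sd = 2))
    expect_equal(fi$loglik, f0$loglik, tolerance = 1e-6)
    expect_equal(coef(fi), coef(f0), tolerance = 1e-4)
  }
  # line segment between two random points never exceeds the endpoint max
  set.seed(5)
  b1 <- rnorm(4); b2 <- rnorm(4)
  lls <- vapply(seq(0, 1, length.out = 11), function(s)
    mnl_loglik_grad(dat, s * b1 + (1 - s) * b2)$loglik, numeric(1))
  expect_gte(min(lls[c(1, 11)]), min(lls) - 1e-9)
  chord <- vapply(seq(0, 1, length.out = 11), function(s)
    s * lls[11] + (1 - s) * lls[1], numeric(1))
  expect_true(all(lls >= chord - 1e-9))
})

test_that("clustered standard errors are computed on request", {
  dat <- make_tiny_data(tiny_space(), beta = c(0.5, -0.3, 0.2),
                        n_resp = 60, n_tasks = 5, seed = 13)
  fit <- fit_mnl(dat, cluster_se = TRUE)
  expect_false(is.null(fit$se_cluster))
  expect_true(all(is.finite(fit$se_cluster)))
})
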