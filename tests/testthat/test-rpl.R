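test_that("zero spread collapses the simulated likelihood to the MNL", {
  dat <- make_tiny_data(tiny_space(), beta = c(0.6, -0.3, 0.4),
                        n_resp = 25, n_tasks = 4, asc = -1, seed = 31)
  K <- ncol(dat$X)
  mu <- c(0.5, -0.2, 0.3)
  asc <- -0.8
  mnl_ll <- mnl_loglik_grad(dat, c(mu, asc))$loglik
  for (R in c(1, 17, 64)) {
    plan <- suppressWarnings(halton_plan(K, n_draws = R, discard = 10))
    expect_equal(simulated_loglik(dat, mu, rep(0, K), asc, plan), mnl_ll,
                 tolerance = 1e-10)
  }
  # one draw with no discard: the first base-2 point is 1/2, so z = 0 and
  # the single-draw simulated likelihood is again the MNL at mu
  plan1 <- suppressWarnings(halton_plan(1, n_draws = 1, discard = 0))
  sp1 <- attribute_space(list(x = c("hi", "lo")))
  dat1 <- make_tiny_data(sp1, beta = 0.5, n_resp = 10, n_tasks = 3,
                         optout = FALSE, seed = 4)
  expect_equal(simulated_loglik(dat1, 0.5, 0.7, plan = plan1,
                                optout_asc = FALSE),
               mnl_loglik_grad(dat1, 0.5, optout_asc = FALSE)$loglik,
               tolerance = 1e-12)
})

test_that("simulated likelihood matches the brute-force panel oracle", {
  dat <- make_tiny_data(tiny_space(), beta = c(0.6, -0.3, 0.4),
                        n_resp = 5, n_tasks = 3, asc = -1, seed = 11)
  K <- ncol(dat$X)
  plan <- suppressWarnings(halton_plan(K, n_draws = 7, discard = 10))
  Z <- vapply(c(2, 3, 5), function(b)
    qnorm(halton_sequence(b, 7, discard = 10)), numeric(7))
  mu <- c(0.4, -0.5, 0.2)
  sg <- c(0.6, 0.3, 0.9)
  expect_equal(simulated_loglik(dat, mu, sg, -0.7, plan),
               oracle_simulated_loglik(dat, mu, sg, -0.7, t(Z)),
               tolerance = 1e-10)
})

test_that("the analytic simulated-likelihood gradient matches differences", {
  dat <- make_tiny_data(tiny_space(), beta = c(0.6, -0.3, 0.4),
                        n_resp = 12, n_tasks = 3, asc = -1, seed = 17)
  K <- ncol(dat$X)
  plan <- suppressWarnings(halton_plan(K, n_draws = 25, discard = 10))
  st <- dcekit:::.rpl_setup(dat, colnames(dat$X), plan, TRUE)
  mu <- c(0.3, -0.2, 0.5); sg <- c(0.4, 0.6, 0.2); fx <- -0.9
  ev <- dcekit:::.rpl_eval(dat, mu, sg, fx, st, want_grad = TRUE)
  g <- c(ev$grad_mu, ev$grad_sg, ev$grad_fix)
  par <- c(mu, sg, fx)
  h <- 1e-6
  g_fd <- vapply(seq_along(par), function(j) {
    e <- numeric(length(par)); e[j] <- h
    up <- par + e; dn <- par - e
    (dcekit:::.rpl_eval(dat, up[1:3], up[4:6], up[7], st)$loglik -
       dcekit:::.rpl_eval(dat, dn[1:3], dn[4:6], dn[7], st)$loglik) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(g - g_fd) / pmax(abs(g_fd), 1)), 1e-5)
})

test_that("simulated likelihood is deterministic and stabilizes in draws", {
  # low dimension: draw noise is far inside half a log-likelihood unit
  sp <- tiny_space()
  des3 <- block_design(search_design(sp, n_sets = 6, n_alts = 2, seed = 4,
                                     n_sweeps = 10), 2, seed = 1)
  beta <- c(0.7, -0.4, 0.5)
  names(beta) <- sp$column_names
  tr <- truth_config("rpl", sp,
                     params = list(mu = beta, sigma = rep(0.5, 3),
                                   optout_asc = -1.5),
                     n_respondents = 200, tasks_per_respondent = 3,
                     seed = 12)
  dat3 <- simulate_choices(des3, tr)
  llA <- simulated_loglik(dat3, beta, rep(0.5, 3), -1.5, halton_plan(3, 500))
  llB <- simulated_loglik(dat3, beta, rep(0.5, 3), -1.5, halton_plan(3, 2000))
  expect_lt(abs(llA - llB), 0.5)

  # 13-dimensional study scale: deterministic, and relative draw noise
  # below 0.2% of the log-likelihood magnitude
  des <- study_design()
  truth <- default_truth("rpl", seed = 3)
  truth$n_respondents <- 200L
  dat <- simulate_choices(des, truth)
  mu <- truth$params$mu
  sg <- truth$params$sigma
  asc <- truth$params$optout_asc
  K <- length(mu)
  ll1 <- simulated_loglik(dat, mu, sg, asc, halton_plan(K, 120))
  ll2 <- simulated_loglik(dat, mu, sg, asc, halton_plan(K, 120))
  expect_identical(ll1, ll2)
  llC <- simulated_loglik(dat, mu, sg, asc, halton_plan(K, 500))
  llD <- simulated_loglik(dat, mu, sg, asc, halton_plan(K, 2000))
  expect_lt(abs(llC - llD) / abs(llD), 0.002)
})

test_that("the fitted mixed logit nests the conditional logit", {
  des <- study_design()
  truth <- default_truth("rpl", seed = 9)
  truth$n_respondents <- 150L
  dat <- simulate_choices(des, truth)
  mnl <- fit_mnl(dat)
  rpl <- fit_rpl(dat, n_draws = 60, hessian = FALSE)
  expect_gte(rpl$loglik, mnl$loglik)
  expect_true(all(rpl$sigma >= 0))
  expect_equal(rpl$aic, 2 * rpl$n_par - 2 * rpl$loglik)
})

test_that("spreads stay small when the truth has none", {
  sp <- tiny_space()
  dat <- make_tiny_data(sp, beta = c(0.7, -0.4, 0.5), n_resp = 250,
                        n_tasks = 5, asc = -1.2, seed = 55)
  rpl <- fit_rpl(dat, n_draws = 150)
  z <- rpl$sigma / rpl$se[paste0("sd:", names(rpl$sigma))]
  not_sig <- is.na(z) | z < 1.96
  expect_gte(sum(not_sig), 2)  # at least 2 of 3 spreads not significant
})

test_that("AIC prefers the MNL when the data have no preference spread", {
  sp <- attribute_space(list(x = c("hi", "lo"), y = c("a", "b")))
  wins <- 0L
  for (rep in 1:20) {
    dat <- make_tiny_data(sp, beta = c(0.8, -0.6), n_resp = 120,
                          n_tasks = 4, asc = -1, seed = 1000 + rep)
    mnl <- fit_mnl(dat)
    rpl <- fit_rpl(dat, n_draws = 60, hessian = FALSE)
    if (mnl$aic <= rpl$aic) wins <- wins + 1L
  }
  expect_gte(wins, 16)  # >= 80% of replicates
})
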