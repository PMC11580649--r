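test_that("the packaged preset reproduces the survey arithmetic", {
  truth <- default_truth("lca", seed = 2)
  expect_equal(truth$n_respondents, 415L)
  expect_equal(truth$tasks_per_respondent, 6L)
  dat <- simulate_choices(study_design(), truth)
  s <- summarize_choices(dat)
  expect_equal(s$n_tasks, 2490L)
  expect_equal(s$n_respondents, 415L)
  # per-class coded truth completes to zero-sum level blocks
  tab <- level_coefficients(truth$space,
                            truth$params$class_betas[, 1])
  sums <- tapply(tab$estimate, tab$attribute, sum)
  expect_equal(as.numeric(sums), rep(0, 6), tolerance = 1e-12)
})

test_that("the calibrated opt-out constant hits the target share band", {
  des <- study_design()
  for (world in c("lca", "rpl")) {
    shares <- vapply(1:10, function(s) {
      truth <- default_truth(world, seed = 3000 + s)
      summarize_choices(simulate_choices(des, truth))$opt_out_share
    }, numeric(1))
    expect_true(all(shares >= 0.04 & shares <= 0.09),
                info = paste(world, paste(round(shares, 3), collapse = " ")))
  }
})

test_that("the membership intercept calibration hits the class-1 share", {
  truth <- default_truth("lca", seed = 5)
  # closed-form expectation over the 8 covariate cells equals the target
  prev <- truth$covariate_prevalence
  cells <- as.matrix(expand.grid(lapply(prev, function(p) 0:1)))
  w <- apply(cells, 1, function(z) prod(ifelse(z == 1, prev, 1 - prev)))
  p1 <- membership_probabilities(cells, truth$params$theta)[, 1]
  expect_equal(sum(w * p1), 0.66, tolerance = 1e-8)
  # large-sample simulated class shares agree
  truth$n_respondents <- 20000L
  dat <- simulate_choices(study_design(), truth)
  tc <- attr(dat, "truth")$true_class
  expect_equal(mean(tc == 1), 0.66, tolerance = 0.02)
})

test_that("simulation is reproducible and respects dominance", {
  des <- study_design()
  truth <- default_truth("lca", seed = 77)
  d1 <- simulate_choices(des, truth)
  d2 <- simulate_choices(des, truth)
  expect_identical(d1$frame, d2$frame)
  d3 <- simulate_choices(des, truth, seed = 78)
  expect_false(identical(d1$frame, d3$frame))

  # a +50 utility on one level dominates every task where it appears
  sp <- tiny_space()
  dom_des <- search_design(sp, n_sets = 4, n_alts = 2, seed = 2,
                           n_sweeps = 5)
  mu <- c(50, 0, 0)  # a=a1 overwhelming
  names(mu) <- sp$column_names
  truth_dom <- truth_config("rpl", sp,
                            params = list(mu = mu, sigma = rep(0, 3),
                                          optout_asc = -1),
                            n_respondents = 200, tasks_per_respondent = 4,
                            seed = 9)
  dat <- simulate_choices(dom_des, truth_dom)
  prof <- dat$frame
  has_a1 <- prof$a == "a1" & prof$opt_out == 0
  has_a1[is.na(has_a1)] <- FALSE
  # tasks containing an a1 alternative: count how often a1 row is chosen
  t_with <- unique(dat$task[has_a1])
  chosen_a1 <- dat$chosen & has_a1
  rate <- length(unique(dat$task[chosen_a1])) / length(t_with)
  expect_gt(rate, 0.99)
})

test_that("empirical choice shares converge to the logit closed form", {
  sp <- tiny_space()
  des <- search_design(sp, n_sets = 3, n_alts = 2, seed = 4, n_sweeps = 10)
  beta <- c(0.7, -0.4, 0.5)
  names(beta) <- sp$column_names
  asc <- -1.2
  truth <- truth_config("rpl", sp,
                        params = list(mu = beta, sigma = rep(0, 3),
                                      optout_asc = asc),
                        n_respondents = 20000, tasks_per_respondent = 3,
                        seed = 31)
  dat <- simulate_choices(des, truth)
  X <- effects_code(sp, des$profiles[, names(sp$attributes)])
  for (s in 1:3) {
    rows <- (s - 1) * 2 + 1:2
    p_true <- choice_probabilities(c(drop(X[rows, ] %*% beta), asc))
    in_set <- dat$frame$task_id == s
    chosen <- dat$frame$choice == 1 & in_set
    counts <- c(sum(chosen & dat$frame$alt_id == "1"),
                sum(chosen & dat$frame$alt_id == "2"),
                sum(chosen & dat$frame$alt_id == "optout"))
    expect_equal(counts / sum(counts), p_true, tolerance = 0.02,
                 ignore_attr = TRUE)
  }
})

test_that("covariate prevalences match their configuration", {
  truth <- default_truth("lca", seed = 51)
  dat <- simulate_choices(study_design(), truth)
  prev <- truth$covariate_prevalence
  emp <- colMeans(dat$covariates)
  sdv <- sqrt(prev * (1 - prev) / truth$n_respondents)
  expect_true(all(abs(emp - prev) <= 3 * sdv))
})

test_that("dataset summaries count opt-outs by definition", {
  truth <- default_truth("lca", seed = 66)
  truth$n_respondents <- 60L
  dat <- simulate_choices(study_design(), truth)
  s <- summarize_choices(dat)
  manual <- sum(dat$frame$choice == 1 & dat$frame$opt_out == 1) / s$n_tasks
  expect_equal(s$opt_out_share, manual)
  expect_equal(s$n_tasks, 360L)
  expect_true(all(s$level_choice_freq$chosen >= 0))
  # shares within each attribute sum to one over chosen designed rows
  agg <- tapply(s$level_choice_freq$share, s$level_choice_freq$attribute, sum)
  expect_equal(as.numeric(agg), rep(1, 6), tolerance = 1e-12)
})
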