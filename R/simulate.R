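# Synthetic respondent generator.
#
# Emulates the survey structure of the risk-tool preference study: 415
# respondents, each assigned one of two design blocks and answering its six
# choice sets (two designed alternatives plus an opt-out), with three binary
# respondent covariates. Ground-truth preferences come from either an RPL
# world (normal random coefficients) or a two-class LCA world whose class
# membership depends on the covariates. Opt-out constants and the
# membership intercept are calibrated by root-finding against closed-form
# expected shares, so the packaged preset reproduces an opt-out share near
# the study's 6.4% and a class-1 share near 66%.

#' The packaged reference design
#'
#' The D-efficient blocked design used by the packaged presets: 12 choice
#' sets of `n_alts` designed alternatives over the study attribute space,
#' found by coordinate exchange at zero priors with a fixed internal seed,
#' then split into two balanced blocks of six. Deterministic and cached.
#'
#' @param n_alts designed alternatives per set (default 2).
#' @return A `choice_design`.
#' @export
study_design <- function(n_alts = 2) {
  key <- paste0("design_", n_alts)
  if (is.null(.dcekit_cache[[key]])) {
    des <- search_design(study_attribute_space(), n_sets = 12,
                         n_alts = n_alts, seed = 8421, n_sweeps = 50,
                         include_optout = TRUE)
    .dcekit_cache[[key]] <- block_design(des, n_blocks = 2, seed = 8421)
  }
  .dcekit_cache[[key]]
}

# expected class-1 share over the 2^p covariate cells (independent margins)
.expected_class1_share <- function(intercept, theta_cov, prev) {
  cells <- as.matrix(expand.grid(lapply(prev, function(p) 0:1)))
  w <- apply(cells, 1, function(z) prod(ifelse(z == 1, prev, 1 - prev)))
  eta <- intercept + drop(cells %*% theta_cov)
  sum(w * stats::plogis(eta))
}

.calibrate_membership_intercept <- function(theta_cov, prev, target) {
  stats::uniroot(function(a) .expected_class1_share(a, theta_cov, prev) - target,
                 c(-10, 10), tol = 1e-10)$root
}

# expected opt-out share of a design under fixed per-class coded betas
.expected_optout_lca <- function(design, class_betas, asc, class_shares) {
  Xd <- .design_coded(design)
  V <- Xd %*% class_betas                    # (S*J) x C
  share <- 0
  for (c in seq_len(ncol(class_betas))) {
    Vs <- matrix(V[, c], nrow = design$n_alts)    # J x S
    po <- exp(asc) / (exp(asc) + colSums(exp(Vs)))
    share <- share + class_shares[c] * mean(po)
  }
  share
}

.expected_optout_rpl <- function(design, mu, sigma, asc, n_draws = 200) {
  Z <- .halton_normal(halton_plan(length(mu), n_draws, discard = 10))
  B <- Z * sigma + mu
  Xd <- .design_coded(design)
  V <- Xd %*% B                              # (S*J) x R
  S <- design$n_sets; J <- design$n_alts
  dim(V) <- c(J, S * n_draws)
  po <- exp(asc) / (exp(asc) + colSums(exp(V)))
  mean(po)
}

.calibrate_optout_asc <- function(f, target) {
  stats::uniroot(function(a) f(a) - target, c(-12, 8), tol = 1e-10)$root
}

#' Assemble a custom ground-truth configuration
#'
#' Low-level constructor behind [default_truth()], for simulation studies
#' with user-chosen parameters. For the `"rpl"` world supply `mu`, `sigma`
#' (both over the coded columns) and a scalar `optout_asc`; for the
#' `"lca"` world supply `class_betas` (coded columns x classes), `theta`
#' (membership matrix including the intercept column) and a per-class
#' `optout_asc` vector.
#'
#' @param world `"rpl"` or `"lca"`.
#' @param space the [attribute_space()] the parameters refer to.
#' @param params named list of world parameters (see above).
#' @param n_respondents respondents to simulate.
#' @param tasks_per_respondent tasks per respondent (must not exceed the
#'   sets per block of the design used at simulation time).
#' @param covariate_prevalence named vector of Bernoulli prevalences for
#'   binary respondent covariates (may be empty).
#' @param seed default RNG seed for [simulate_choices()].
#' @return Object of class `dce_truth`.
#' @export
truth_config <- function(world = c("lca", "rpl"), space, params,
                         n_respondents = 415, tasks_per_respondent = 6,
                         covariate_prevalence = numeric(0), seed = 1) {
  world <- match.arg(world)
  stopifnot(inherits(space, "attribute_space"))
  if (any(covariate_prevalence < 0 | covariate_prevalence > 1))
    stop("covariate prevalences must lie in [0, 1]")
  if (world == "rpl") {
    stopifnot(all(c("mu", "sigma", "optout_asc") %in% names(params)))
    if (any(params$sigma < 0)) stop("sigma must be >= 0")
  } else {
    stopifnot(all(c("class_betas", "theta", "optout_asc") %in% names(params)))
  }
  structure(list(world = world, space = space, design = NULL,
                 n_respondents = as.integer(n_respondents),
                 tasks_per_respondent = as.integer(tasks_per_respondent),
                 covariate_prevalence = covariate_prevalence,
                 params = params,
                 opt_out_target = NA_real_,
                 seed = as.integer(seed)),
            class = "dce_truth")
}

#' Ground-truth presets for the synthetic generator
#'
#' Builds the generator's ground-truth configuration for one of two data
#' worlds. The `"lca"` world uses the packaged two-class study estimates
#' (class-specific level utilities, membership covariate coefficients
#' 0.93 / -0.62 / -0.88 for recent arrival, bachelor-plus education and
#' clinic attendance) with the membership intercept calibrated so the
#' expected class-1 share is 66% at covariate prevalences 30% / 68% / 86%.
#' The `"rpl"` world uses the share-weighted pooled means with all spreads
#' at 0.5. In both worlds the opt-out constant is calibrated by bisection so
#' the expected opt-out share equals `opt_out_target` (default 6.4%) on the
#' reference design.
#'
#' @param world `"lca"` (default) or `"rpl"`.
#' @param design the `choice_design` respondents answer (default
#'   [study_design()]).
#' @param n_respondents number of respondents (study default 415).
#' @param opt_out_target expected share of tasks where the opt-out is
#'   chosen (default 0.064).
#' @param class1_share_target expected share of the first latent class
#'   (default 0.66; `"lca"` world only).
#' @param rpl_sigma spread of every random coefficient in the `"rpl"` world
#'   (default 0.5).
#' @param seed seed stored in the configuration and used by
#'   [simulate_choices()] by default.
#' @return Object of class `dce_truth`.
#' @export
default_truth <- function(world = c("lca", "rpl"), design = study_design(),
                          n_respondents = 415, opt_out_target = 0.064,
                          class1_share_target = 0.66, rpl_sigma = 0.5,
                          seed = 1) {
  world <- match.arg(world)
  space <- design$space
  prev <- .study_covariate_prevalence
  blocks <- split(seq_len(design$n_sets), design$block)
  tasks <- length(blocks[[1]])

  cb <- .study_class_betas_coded(space)
  if (world == "lca") {
    theta_cov <- .study_theta_covariates
    a <- .calibrate_membership_intercept(theta_cov, prev, class1_share_target)
    theta <- matrix(c(a, theta_cov), nrow = 1,
                    dimnames = list("class1",
                                    c("(intercept)", names(theta_cov))))
    shares <- c(class1_share_target, 1 - class1_share_target)
    asc <- .calibrate_optout_asc(function(a)
      .expected_optout_lca(design, cb, a, shares), opt_out_target)
    params <- list(class_betas = cb, theta = theta,
                   optout_asc = c(class1 = asc, class2 = asc),
                   expected_class_shares = shares)
  } else {
    mu <- drop(cb %*% .study_class_shares)
    sigma <- rep(rpl_sigma, length(mu))
    names(sigma) <- names(mu)
    asc <- .calibrate_optout_asc(function(a)
      .expected_optout_rpl(design, mu, sigma, a), opt_out_target)
    params <- list(mu = mu, sigma = sigma, optout_asc = asc)
  }
  structure(list(world = world, space = space, design = design,
                 n_respondents = as.integer(n_respondents),
                 tasks_per_respondent = tasks,
                 covariate_prevalence = prev,
                 params = params,
                 opt_out_target = opt_out_target,
                 seed = as.integer(seed)),
            class = "dce_truth")
}

#' @export
print.dce_truth <- function(x, ...) {
  cat("Synthetic truth (", x$world, " world): ", x$n_respondents,
      " respondents x ", x$tasks_per_respondent, " tasks, opt-out target ",
      sprintf("%.1f%%", 100 * x$opt_out_target), "\n", sep = "")
  invisible(x)
}

#' Simulate panel choice data from a ground truth
#'
#' Draws a synthetic survey: respondents are assigned design blocks
#' round-robin, binary covariates are drawn from the configured
#' prevalences, preferences are drawn per world (normal coefficients, or a
#' latent class drawn from the membership logit), and each task's choice is
#' drawn from the logit kernel over the designed alternatives plus the
#' opt-out. Fully reproducible from the seed.
#'
#' @param design a `choice_design`; must share the truth's attribute space.
#' @param truth a `dce_truth` from [default_truth()].
#' @param seed RNG seed (default: the truth's stored seed).
#' @return A [choice_data()] object; the generating configuration and true
#'   per-respondent assignments are attached as `attr(, "truth")`.
#' @export
simulate_choices <- function(design, truth, seed = truth$seed) {
  stopifnot(inherits(design, "choice_design"), inherits(truth, "dce_truth"))
  if (!identical(design$space$column_names, truth$space$column_names))
    stop("design and truth use different attribute spaces")
  space <- design$space
  n <- truth$n_respondents
  J <- design$n_alts
  K <- space$n_columns
  set.seed(as.integer(seed) %% .Machine$integer.max)

  blocks <- split(seq_len(design$n_sets), design$block)
  B <- length(blocks)
  Tn <- truth$tasks_per_respondent
  if (any(vapply(blocks, length, 0L) < Tn))
    stop("tasks_per_respondent (", Tn, ") exceeds the sets available in a block")
  resp_block <- rep_len(seq_len(B), n)

  prev <- truth$covariate_prevalence
  p <- length(prev)
  cov <- matrix(stats::rbinom(n * p, 1, rep(prev, each = n)), n, p,
                dimnames = list(NULL, names(prev)))

  if (truth$world == "rpl") {
    Z <- matrix(stats::rnorm(K * n), K, n)
    Beta <- truth$params$mu + truth$params$sigma * Z
    asc_n <- rep(truth$params$optout_asc, n)
    true_class <- NULL
  } else {
    pi1 <- membership_probabilities(cov, truth$params$theta)[, 1]
    true_class <- ifelse(stats::runif(n) < pi1, 1L, 2L)
    Beta <- truth$params$class_betas[, true_class, drop = FALSE]
    asc_n <- truth$params$optout_asc[true_class]
  }

  Xd <- .design_coded(design)
  u_choice <- matrix(stats::runif(n * Tn), n, Tn)

  chosen_alt <- matrix(0L, n, Tn)  # 1..J designed, J+1 = opt-out
  for (b in seq_len(B)) {
    rb <- which(resp_block == b)
    if (!length(rb)) next
    for (ti in seq_len(Tn)) {
      s <- blocks[[b]][ti]
      rows <- (s - 1L) * J + seq_len(J)
      V <- t(Xd[rows, , drop = FALSE] %*% Beta[, rb, drop = FALSE]) # n_b x J
      U <- cbind(V, asc_n[rb])
      m <- U[cbind(seq_len(nrow(U)), max.col(U, ties.method = "first"))]
      P <- exp(U - m)
      P <- P / rowSums(P)
      cum <- P
      for (j in 2:ncol(P)) cum[, j] <- cum[, j - 1L] + P[, j]
      chosen_alt[rb, ti] <- pmin(1L + rowSums(u_choice[rb, ti] > cum),
                                 ncol(cum))
    }
  }

  # assemble the long frame: J designed rows + 1 opt-out row per task
  rows_per_task <- J + 1L
  n_rows <- n * Tn * rows_per_task
  resp_idx <- rep(seq_len(n), each = Tn * rows_per_task)
  task_idx <- rep(rep(seq_len(Tn), each = rows_per_task), times = n)
  alt_idx <- rep(seq_len(rows_per_task), times = n * Tn)
  sets_mat <- do.call(rbind, blocks)            # B x Tn
  set_of_row <- sets_mat[cbind(resp_block[resp_idx], task_idx)]
  is_optout <- alt_idx == rows_per_task

  df <- data.frame(resp_id = sprintf("R%05d", resp_idx),
                   task_id = task_idx,
                   alt_id = ifelse(is_optout, "optout",
                                   as.character(alt_idx)),
                   opt_out = as.integer(is_optout),
                   choice = as.integer(alt_idx ==
                     chosen_alt[cbind(resp_idx, task_idx)]),
                   stringsAsFactors = FALSE)
  prof <- design$profiles[, names(space$attributes), drop = FALSE]
  des_prof <- prof[(set_of_row - 1L) * J + pmin(alt_idx, J), , drop = FALSE]
  des_prof[is_optout, ] <- NA
  df <- cbind(df, des_prof, cov[resp_idx, , drop = FALSE])
  rownames(df) <- NULL

  out <- choice_data(df, space, covariates = colnames(cov))
  attr(out, "truth") <- list(world = truth$world, config = truth,
                             true_class = true_class,
                             block_of_respondent = resp_block)
  out
}
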