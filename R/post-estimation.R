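# Headline outputs of a fitted choice model: relative attribute importance,
# scenario utilities, predicted uptake against the opt-out, and model
# comparison tables.

.importance_from_full <- function(full) {
  rng <- vapply(full, function(b) max(b) - min(b), numeric(1))
  if (all(rng < 1e-12)) {
    warning("all level coefficients are zero: importance set to uniform")
    return(stats::setNames(rep(100 / length(full), length(full)), names(full)))
  }
  100 * rng / sum(rng)
}

.full_levels_from_beta <- function(space, beta) {
  tab <- level_coefficients(space, beta)
  split(tab$estimate, factor(tab$attribute, levels = names(space$attributes)))
}

#' Relative attribute importance
#'
#' The standard DCE importance measure: each attribute's share of total
#' utility range. With completed (zero-sum) level coefficient sets, the
#' importance of attribute `k` is `(max_l beta_kl - min_l beta_kl)` divided
#' by the sum of those ranges over attributes, times 100. Percentages sum
#' to 100.
#'
#' @param x a fitted model (`mnl_fit`, `rpl_fit`, `lca_fit`) or a named
#'   list of full per-level coefficient vectors, one element per attribute.
#' @param ... unused.
#' @return Named vector of percentages (for `lca_fit`, a matrix with one
#'   column per class).
#' @export
relative_importance <- function(x, ...) UseMethod("relative_importance")

#' @export
relative_importance.default <- function(x, ...) {
  if (!is.list(x) || is.null(names(x)))
    stop("need a fitted model or a named list of level coefficient vectors")
  .importance_from_full(x)
}

#' @export
relative_importance.mnl_fit <- function(x, ...) {
  .importance_from_full(.full_levels_from_beta(x$space, stats::coef(x)))
}

#' @export
relative_importance.rpl_fit <- function(x, ...) {
  beta <- c(x$mu, x$fixed)
  .importance_from_full(.full_levels_from_beta(x$space, beta))
}

#' @export
relative_importance.lca_fit <- function(x, ...) {
  out <- vapply(seq_len(x$n_classes), function(c)
    .importance_from_full(.full_levels_from_beta(x$space, x$class_betas[, c])),
    numeric(length(x$space$attributes)))
  colnames(out) <- colnames(x$class_betas)
  out
}

#' Define a product scenario
#'
#' A scenario assigns one level to every attribute of a space: one full
#' product configuration for utility and uptake computation.
#'
#' @param space an [attribute_space()].
#' @param levels named character vector or list, attribute -> level label.
#' @param name optional scenario name.
#' @return Named character vector with attribute `scenario_name`, validated
#'   against the space.
#' @export
scenario <- function(space, levels, name = NULL) {
  stopifnot(inherits(space, "attribute_space"))
  levels <- unlist(levels)
  miss <- setdiff(names(space$attributes), names(levels))
  if (length(miss))
    stop("scenario is missing attribute(s): ", paste(miss, collapse = ", "))
  levels <- levels[names(space$attributes)]
  effects_code(space, levels)  # validates level labels
  structure(levels, scenario_name = name)
}

#' Scenario utility
#'
#' The systematic utility of a scenario: the sum over attributes of the
#' coefficient of the scenario's level (the opt-out constant is excluded).
#'
#' @param x a fitted model, or a data frame with columns `attribute`,
#'   `level`, `estimate` (e.g. from [level_coefficients()]).
#' @param scen named character vector, attribute -> level label.
#' @param ... unused.
#' @return Scalar utility (for `lca_fit`, a vector with one entry per
#'   class; for `rpl_fit`, the utility at the coefficient means).
#' @export
scenario_utility <- function(x, scen, ...) UseMethod("scenario_utility")

#' @export
scenario_utility.data.frame <- function(x, scen, ...) {
  stopifnot(all(c("attribute", "level", "estimate") %in% names(x)))
  tot <- 0
  for (a in names(scen)) {
    hit <- x$attribute == a & x$level == scen[[a]]
    if (sum(hit) != 1L)
      stop("unknown level '", scen[[a]], "' for attribute '", a, "'")
    tot <- tot + x$estimate[hit]
  }
  tot
}

#' @export
scenario_utility.mnl_fit <- function(x, scen, ...) {
  drop(effects_code(x$space, scen) %*%
         stats::coef(x)[x$space$column_names])
}

#' @export
scenario_utility.rpl_fit <- function(x, scen, ...) {
  beta <- c(x$mu, x$fixed)
  drop(effects_code(x$space, scen) %*% beta[x$space$column_names])
}

#' @export
scenario_utility.lca_fit <- function(x, scen, ...) {
  v <- drop(effects_code(x$space, scen) %*%
              x$class_betas[x$space$column_names, , drop = FALSE])
  stats::setNames(v, colnames(x$class_betas))
}

.optout_asc_of <- function(fit) {
  cf <- stats::coef(fit)
  if ("optout_asc" %in% names(cf)) unname(cf["optout_asc"]) else 0
}

#' Predicted uptake of a scenario
#'
#' The model-simulated probability that the configured tool scenario is
#' chosen rather than opting out, in a choice situation holding the
#' scenario (plus any `competitors`) and the opt-out alternative. For the
#' conditional logit this is `plogis(V - ASC_optout)`; the mixed logit
#' averages that probability over its Halton draws; the latent-class model
#' mixes the per-class probabilities by the fitted class shares. With
#' competitors present, uptake is the probability of choosing any designed
#' alternative (one minus the opt-out probability).
#'
#' @param fit a fitted `mnl_fit`, `rpl_fit` or `lca_fit`.
#' @param scen named character vector, attribute -> level label.
#' @param competitors optional list of additional scenarios offered
#'   alongside `scen`.
#' @param name optional scenario label for the output.
#' @return One-row data frame with columns `scenario`, `uptake`, `model`,
#'   `n_draws`.
#' @export
predict_uptake <- function(fit, scen, competitors = NULL, name = NULL) {
  stopifnot(inherits(fit, "dce_fit"))
  space <- fit$space
  scens <- c(list(scen), if (!is.null(competitors)) competitors)
  Xs <- do.call(rbind, lapply(scens, function(s)
    effects_code(space, s[names(space$attributes)])))

  uptake_given <- function(beta_coded, asc) {
    v <- drop(Xs %*% beta_coded)
    p <- choice_probabilities(c(v, asc))
    1 - p[length(p)]
  }

  n_draws <- 1L
  if (inherits(fit, "rpl_fit")) {
    Z <- .halton_normal(fit$plan)
    n_draws <- fit$plan$n_draws
    asc <- if (length(fit$fixed) && "optout_asc" %in% names(fit$fixed))
      unname(fit$fixed["optout_asc"]) else 0
    beta_base <- stats::setNames(numeric(space$n_columns), space$column_names)
    fixed_coded <- setdiff(names(fit$fixed), "optout_asc")
    beta_base[fixed_coded] <- fit$fixed[fixed_coded]
    up <- mean(vapply(seq_len(n_draws), function(r) {
      b <- beta_base
      b[fit$random] <- fit$mu + fit$sigma * Z[, r]
      uptake_given(b[space$column_names], asc)
    }, numeric(1)))
  } else if (inherits(fit, "lca_fit")) {
    asc_row <- if (fit$optout_asc) fit$class_betas["optout_asc", ] else
      rep(0, fit$n_classes)
    ups <- vapply(seq_len(fit$n_classes), function(c)
      uptake_given(fit$class_betas[space$column_names, c], asc_row[c]),
      numeric(1))
    up <- sum(fit$class_shares * ups)
  } else {
    up <- uptake_given(stats::coef(fit)[space$column_names],
                       .optout_asc_of(fit))
  }

  data.frame(scenario = if (!is.null(name)) name else
               if (!is.null(attr(scen, "scenario_name")))
                 attr(scen, "scenario_name") else "scenario",
             uptake = up, model = fit$model, n_draws = n_draws,
             stringsAsFactors = FALSE)
}

#' Model comparison table
#'
#' Side-by-side fit statistics for a set of fitted choice models: parameter
#' count, log-likelihood, AIC (`2K - 2LL`) and AIC/N, sorted by ascending
#' AIC.
#'
#' @param ... fitted `dce_fit` objects (named arguments become row labels).
#' @param n denominator for AIC/N: `"choice_tasks"` (default) or
#'   `"respondents"`.
#' @return Data frame with one row per model.
#' @export
model_comparison <- function(..., n = c("choice_tasks", "respondents")) {
  n <- match.arg(n)
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1]]) &&
      !inherits(fits[[1]], "dce_fit")) fits <- fits[[1]]
  if (!length(fits)) stop("no fitted models supplied")
  nm <- names(fits)
  if (is.null(nm)) nm <- rep("", length(fits))
  lab <- ifelse(nm == "", vapply(fits, function(f) f$model, ""), nm)
  out <- data.frame(model = lab,
                    K = vapply(fits, function(f) f$n_par, numeric(1)),
                    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
                    stringsAsFactors = FALSE)
  out$AIC <- 2 * out$K - 2 * out$loglik
  denom <- vapply(fits, function(f)
    switch(n, choice_tasks = f$n_tasks, respondents = f$n_resp), numeric(1))
  out$AIC_per_N <- out$AIC / denom
  out <- out[order(out$AIC), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Significance stars
#'
#' Star annotation convention of the study's coefficient tables:
#' `***` for p < 0.01, `**` for p < 0.05, `*` for p < 0.10.
#'
#' @param p vector of p-values.
#' @return Character vector of star strings.
#' @export
significance_stars <- function(p) .stars(p)
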