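# S3 methods shared by the fitted-model family.

# term/estimate/se/z/p/stars table
.coef_table <- function(fit) {
  est <- stats::coef(fit)
  se <- fit$se
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             z = unname(z), p = unname(p), stars = .stars(unname(p)),
             stringsAsFactors = FALSE)
}

#' @export
coef.dce_fit <- function(object, ...) object$coefficients

#' @export
logLik.dce_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_par, nobs = object$n_tasks,
            class = "logLik")
}

#' @export
vcov.dce_fit <- function(object, ...) object$vcov

#' @export
print.dce_fit <- function(x, ...) {
  cat(x$model, "choice model:", x$n_resp, "respondents,", x$n_tasks,
      "tasks\n")
  cat("log-likelihood", format(x$loglik, digits = 8), " AIC",
      format(x$aic, digits = 8),
      if (!x$converged) " (NOT converged)", "\n")
  print(round(stats::coef(x), 4))
  invisible(x)
}

#' @export
summary.dce_fit <- function(object, ...) {
  out <- list(model = object$model, table = .coef_table(object),
              loglik = object$loglik, aic = object$aic,
              n_resp = object$n_resp, n_tasks = object$n_tasks,
              converged = object$converged)
  class(out) <- "summary.dce_fit"
  out
}

#' @export
print.summary.dce_fit <- function(x, ...) {
  cat(x$model, "choice model —", x$n_resp, "respondents,", x$n_tasks,
      "tasks\n\n")
  tb <- x$table
  tb$estimate <- sprintf("% .4f", tb$estimate)
  tb$se <- sprintf("%.4f", tb$se)
  tb$z <- sprintf("% .2f", tb$z)
  tb$p <- sprintf("%.4f", tb$p)
  print(tb, row.names = FALSE, right = FALSE)
  cat("\nlog-likelihood:", format(x$loglik, digits = 8),
      "  AIC:", format(x$aic, digits = 8), "\n")
  cat("Signif.: *** p<0.01, ** p<0.05, * p<0.10\n")
  if (!x$converged) cat("WARNING: optimizer did not converge\n")
  invisible(x)
}

#' @export
print.lca_fit <- function(x, ...) {
  cat("Latent-class (", x$n_classes, "-class) conditional logit: ",
      x$n_resp, " respondents, ", x$n_tasks, " tasks\n", sep = "")
  cat("class shares:",
      paste(sprintf("%s %.1f%%", names(x$class_shares),
                    100 * x$class_shares), collapse = ", "), "\n")
  cat("log-likelihood", format(x$loglik, digits = 8), " AIC",
      format(x$aic, digits = 8), " AIC/N",
      format(x$aic_per_n, digits = 4),
      paste0("(N = ", x$aic_n_convention, ")"),
      if (!x$converged) " (NOT converged)", "\n\n")
  cat("Per-class coefficients:\n")
  print(round(x$class_betas, 4))
  if (x$n_classes > 1) {
    cat("\nClass probability model (last class = Ref):\n")
    print(round(x$theta, 4))
  }
  invisible(x)
}

#' Predict method for fitted choice models
#'
#' Dispatches to [predict_uptake()]: predicted probability of choosing the
#' given scenario over opting out.
#'
#' @param object a fitted `dce_fit`.
#' @param scenario named character vector, attribute -> level label.
#' @param ... passed to [predict_uptake()].
#' @return See [predict_uptake()].
#' @export
predict.dce_fit <- function(object, scenario, ...) {
  predict_uptake(object, scenario, ...)
}
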