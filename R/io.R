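# File formats: long-format choice CSV, design CSV/JSON, fit reports.
# CSV dialect: UTF-8, comma separated, header required, "." decimal; level
# labels are matched case-sensitively after whitespace trimming.

#' Read long-format choice data from CSV
#'
#' Expects one row per alternative with columns `resp_id`, `task_id`,
#' `alt_id`, `choice`, one column per attribute of `space` (level labels;
#' blank on opt-out rows), an optional `opt_out` flag and optional
#' covariate columns. Validation (exactly one chosen row per task, known
#' level labels) happens in [choice_data()].
#'
#' @param path CSV file path.
#' @param space an [attribute_space()].
#' @param covariates optional character vector of covariate column names.
#' @return A [choice_data()] object.
#' @export
read_choice_csv <- function(path, space, covariates = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        check.names = FALSE)
  need <- c("resp_id", "task_id", "alt_id", "choice")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "))
  for (a in intersect(names(space$attributes), names(df)))
    df[[a]] <- trimws(df[[a]])
  choice_data(df, space, covariates = covariates)
}

#' Write long-format choice data to CSV
#'
#' @param data a [choice_data()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_choice_csv <- function(data, path) {
  stopifnot(inherits(data, "choice_data"))
  utils::write.csv(data$frame, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a choice design to CSV / JSON
#'
#' The CSV holds one row per designed alternative (`set`, `block`, `alt`,
#' one level-label column per attribute); the JSON adds the D-error, the
#' search seed and a schema tag.
#'
#' @param design a `choice_design`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_design_csv <- function(design, path) {
  stopifnot(inherits(design, "choice_design"))
  out <- design$profiles
  out <- cbind(set = out$set, block = design$block[out$set],
               out[, setdiff(names(out), "set"), drop = FALSE])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
write_design_json <- function(design, path) {
  stopifnot(inherits(design, "choice_design"))
  j <- list(schema = "dcekit/choice_design/1",
            seed = design$seed,
            d_error = design$d_error,
            n_sets = design$n_sets,
            n_alts = design$n_alts,
            block = design$block,
            profiles = design$profiles)
  jsonlite::write_json(j, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a design written by [write_design_json()]
#'
#' @param path JSON file path.
#' @param space the [attribute_space()] the design was built on.
#' @return A `choice_design`.
#' @export
read_design_json <- function(path, space) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  prof <- as.data.frame(j$profiles, stringsAsFactors = FALSE)
  structure(list(profiles = prof,
                 block = as.integer(j$block),
                 n_sets = as.integer(j$n_sets),
                 n_alts = as.integer(j$n_alts),
                 d_error = as.numeric(j$d_error),
                 seed = j$seed,
                 space = space),
            class = "choice_design")
}

#' Write fit reports
#'
#' Writes two files from a fitted model: `<stem>.json` (machine readable:
#' schema tag, fit statistics, the full parameter table with estimates,
#' standard errors, z, p and significance stars; latent-class fits add the
#' per-class coefficient matrix, the class-probability model with its
#' reference-class annotation, class shares and AIC/N) and `<stem>.txt`
#' (an aligned human-readable table).
#'
#' @param fit a fitted `dce_fit`.
#' @param stem output path without extension.
#' @return Character vector of the two file paths, invisibly.
#' @export
write_results <- function(fit, stem) {
  stopifnot(inherits(fit, "dce_fit"))
  tb <- .coef_table(fit)
  j <- list(schema = "dcekit/fit/1",
            model = fit$model,
            K = fit$n_par,
            loglik = fit$loglik,
            aic = fit$aic,
            n_respondents = fit$n_resp,
            n_tasks = fit$n_tasks,
            converged = fit$converged,
            parameters = tb)
  if (inherits(fit, "rpl_fit"))
    j$halton_plan <- list(primes = fit$plan$primes,
                          n_draws = fit$plan$n_draws,
                          discard = fit$plan$discard)
  if (inherits(fit, "lca_fit")) {
    j$n_classes <- fit$n_classes
    j$class_shares <- as.list(stats::setNames(fit$class_shares,
                                              colnames(fit$class_betas)))
    j$aic_per_n <- fit$aic_per_n
    j$aic_n_convention <- fit$aic_n_convention
    if (fit$n_classes > 1) {
      th <- as.data.frame(fit$theta)
      th <- cbind(class = rownames(fit$theta), th,
                  reference = paste0("class", fit$n_classes))
      j$class_probability_model <- th
    }
  }
  json_path <- paste0(stem, ".json")
  txt_path <- paste0(stem, ".txt")
  jsonlite::write_json(j, json_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")

  con <- file(txt_path, "w")
  on.exit(close(con))
  writeLines(sprintf("%s choice model (%d respondents, %d tasks)",
                     fit$model, fit$n_resp, fit$n_tasks), con)
  writeLines(sprintf("log-likelihood %.4f  AIC %.4f%s", fit$loglik, fit$aic,
                     if (!fit$converged) "  [NOT converged]" else ""), con)
  if (inherits(fit, "lca_fit")) {
    writeLines(sprintf("AIC/N = %.4f (N = %s)", fit$aic_per_n,
                       fit$aic_n_convention), con)
    writeLines(sprintf("class shares: %s",
                       paste(sprintf("%.1f%%", 100 * fit$class_shares),
                             collapse = " / ")), con)
  }
  writeLines("", con)
  fmt <- sprintf("%%-%ds %%10s %%8s %%s", max(nchar(tb$term)) + 2L)
  writeLines(sprintf(fmt, "term", "estimate", "se", ""), con)
  for (i in seq_len(nrow(tb)))
    writeLines(sprintf(fmt, tb$term[i], sprintf("%.4f", tb$estimate[i]),
                       sprintf("%.4f", tb$se[i]), tb$stars[i]), con)
  if (inherits(fit, "lca_fit") && fit$n_classes > 1) {
    writeLines("", con)
    writeLines("Theta in the class probability model (last class = Ref):", con)
    for (r in rownames(fit$theta))
      writeLines(paste0("  ", r, ": ",
                        paste(sprintf("%s=%.4f", colnames(fit$theta),
                                      fit$theta[r, ]), collapse = ", ")), con)
  }
  writeLines("", con)
  writeLines("Signif.: *** p<0.01, ** p<0.05, * p<0.10", con)
  invisible(c(json_path, txt_path))
}
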