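#' Assemble a panel choice dataset
#'
#' Builds the estimation container from long-format data: one row per
#' alternative of each choice task, with exactly one chosen row per task.
#' Designed alternatives carry attribute level labels which are effects
#' coded against `space`; an opt-out row carries no profile (all-zero coded
#' columns) and is identified by the `opt_out` column. Repeated tasks by the
#' same respondent form the panel structure the mixed-logit and latent-class
#' models exploit.
#'
#' @param df data frame with columns `resp_id`, `task_id`, `alt_id`,
#'   `choice` (0/1), optionally `opt_out` (0/1), one column per attribute of
#'   `space` (level labels; ignored on opt-out rows), and any respondent
#'   covariate columns.
#' @param space an [attribute_space()].
#' @param covariates character vector of covariate column names (binary 0/1,
#'   constant within respondent), or `NULL`.
#' @return Object of class `choice_data`.
#' @export
choice_data <- function(df, space, covariates = NULL) {
  stopifnot(inherits(space, "attribute_space"))
  need <- c("resp_id", "task_id", "alt_id", "choice")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$opt_out)) df$opt_out <- 0L
  df$opt_out <- as.integer(df$opt_out != 0)
  df$choice <- as.integer(df$choice != 0)

  # stable ordering: respondent, task, then original row order
  ord <- order(match(df$resp_id, unique(df$resp_id)),
               match(paste(df$resp_id, df$task_id),
                     unique(paste(df$resp_id, df$task_id))))
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL

  task_key <- paste(df$resp_id, df$task_id, sep = "\r")
  task <- match(task_key, unique(task_key))
  n_tasks <- max(task)
  chosen_per_task <- tabulate(task[df$choice == 1], nbins = n_tasks)
  if (any(chosen_per_task != 1L)) {
    bad <- which(chosen_per_task != 1L)[1]
    key <- unique(task_key)[bad]
    key <- sub("\r", ", task ", key)
    stop("each task needs exactly one chosen alternative; violated at ",
         "respondent ", key)
  }

  X <- matrix(0, nrow(df), space$n_columns,
              dimnames = list(NULL, space$column_names))
  des <- df$opt_out == 0L
  if (any(des))
    X[des, ] <- effects_code(space, df[des, names(space$attributes), drop = FALSE])

  resp_ids <- unique(df$resp_id)
  resp_of_task <- match(sub("\r.*$", "", unique(task_key)), resp_ids)

  sizes <- tabulate(task, nbins = n_tasks)
  J <- if (length(unique(sizes)) == 1L) sizes[1] else NA_integer_

  cov <- NULL
  if (!is.null(covariates) && length(covariates)) {
    miss <- setdiff(covariates, names(df))
    if (length(miss))
      stop("covariate column(s) not found: ", paste(miss, collapse = ", "))
    first_row <- match(resp_ids, df$resp_id)
    cov <- as.matrix(df[first_row, covariates, drop = FALSE])
    storage.mode(cov) <- "double"
    rownames(cov) <- as.character(resp_ids)
    if (!all(cov %in% c(0, 1)))
      stop("covariates must be binary 0/1")
    for (v in covariates) {
      agg <- tapply(df[[v]], df$resp_id, function(z) length(unique(z)))
      if (any(agg > 1))
        stop("covariate '", v, "' varies within a respondent")
    }
  }

  structure(list(X = X,
                 optout = as.numeric(df$opt_out),
                 chosen = df$choice == 1L,
                 task = task,
                 resp_of_task = resp_of_task,
                 resp_ids = resp_ids,
                 n_tasks = n_tasks,
                 n_resp = length(resp_ids),
                 J = J,
                 covariates = cov,
                 space = space,
                 frame = df),
            class = "choice_data")
}

#' @export
print.choice_data <- function(x, ...) {
  cat("Choice dataset:", x$n_resp, "respondents,", x$n_tasks, "tasks,",
      nrow(x$X), "alternative rows",
      if (!is.na(x$J)) paste0("(", x$J, " per task)"), "\n")
  cat("  opt-out chosen in ",
      sprintf("%.1f%%", 100 * mean(x$optout[x$chosen])), " of tasks\n", sep = "")
  if (!is.null(x$covariates))
    cat("  covariates:", paste(colnames(x$covariates), collapse = ", "), "\n")
  invisible(x)
}

#' Summarize a choice dataset
#'
#' Descriptive summary of a panel choice dataset: respondent and task
#' counts, the share of tasks where the opt-out was chosen, per-level choice
#' frequencies among chosen designed alternatives, and covariate
#' prevalences.
#'
#' @param data a [choice_data()] object.
#' @return A list of class `choice_data_summary` with elements
#'   `n_respondents`, `n_tasks`, `opt_out_share`, `level_choice_freq`
#'   (data frame), and `covariate_prevalence` (named vector, possibly empty).
#' @export
summarize_choices <- function(data) {
  stopifnot(inherits(data, "choice_data"))
  chosen_rows <- which(data$chosen)
  des <- chosen_rows[data$optout[chosen_rows] == 0]
  freq <- NULL
  if (length(des)) {
    prof <- decode_profiles(data$space, data$X[des, , drop = FALSE])
    freq <- do.call(rbind, lapply(names(prof), function(a) {
      tb <- table(factor(prof[[a]], levels = data$space$attributes[[a]]))
      data.frame(attribute = a, level = names(tb),
                 chosen = as.integer(tb),
                 share = as.numeric(tb) / length(des),
                 stringsAsFactors = FALSE)
    }))
    rownames(freq) <- NULL
  }
  prev <- if (is.null(data$covariates)) stats::setNames(numeric(0), character(0))
          else colMeans(data$covariates)
  structure(list(n_respondents = data$n_resp,
                 n_tasks = data$n_tasks,
                 opt_out_share = mean(data$optout[data$chosen]),
                 level_choice_freq = freq,
                 covariate_prevalence = prev),
            class = "choice_data_summary")
}

#' @export
print.choice_data_summary <- function(x, ...) {
  cat("Respondents:", x$n_respondents, " Tasks:", x$n_tasks, "\n")
  cat(sprintf("Opt-out share: %.1f%%\n", 100 * x$opt_out_share))
  if (length(x$covariate_prevalence)) {
    cat("Covariate prevalence:\n")
    for (v in names(x$covariate_prevalence))
      cat(sprintf("  %s: %.1f%%\n", v, 100 * x$covariate_prevalence[v]))
  }
  invisible(x)
}

# full model matrix: coded columns plus opt-out alternative-specific constant
.model_matrix <- function(data, optout_asc = TRUE) {
  if (optout_asc) cbind(data$X, optout_asc = data$optout) else data$X
}
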