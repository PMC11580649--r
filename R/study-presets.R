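# Packaged study vocabulary: the MySTIRisk HIV/STI risk-tool DCE.
# Six attributes (cost, speed of results, accuracy, anonymity, application
# type, additional services) with 3/3/4/3/2/4 levels -> 13 effects-coded
# columns. Published two-class latent-class estimates are packaged as the
# synthetic-truth preset for recovery studies.

.dcekit_cache <- new.env(parent = emptyenv())

#' The MySTIRisk study attribute space
#'
#' Attributes and levels of the sexual-health AI risk-tool preference survey
#' that this package's synthetic generator emulates: cost (Free/$5/$10),
#' speed of results, accuracy band, anonymity/login requirement, application
#' type, and additional services bundled with the risk report. Loaded from
#' the packaged JSON fixture.
#'
#' @return An [attribute_space()] with 6 attributes and 13 coded columns.
#' @export
study_attribute_space <- function() {
  if (is.null(.dcekit_cache$space)) {
    path <- system.file("extdata", "mystirisk_attributes.json",
                        package = "dcekit", mustWork = TRUE)
    .dcekit_cache$space <- read_attribute_space(path)
  }
  .dcekit_cache$space
}

# Published two-class latent-class level coefficients (synthetic-truth
# preset). Class 1 "Precisionists" is accuracy-driven; class 2 "Economists"
# is cost-driven. Values are per-level utilities under effects coding; each
# attribute block sums to ~0 up to print rounding.
.study_class_levels <- function() {
  list(
    cost = cbind(c(0.70, -0.11, -0.59), c(2.48, -0.90, -1.58)),
    speed = cbind(c(-0.10, 0.23, -0.14), c(-0.11, 0.15, -0.05)),
    accuracy = cbind(c(-1.00, -0.06, -0.03, 1.09), c(-0.36, -0.39, -0.11, 0.86)),
    anonymity = cbind(c(0.02, -0.20, 0.18), c(0.38, -0.37, -0.02)),
    app_type = cbind(c(0.17, -0.17), c(0.02, -0.02)),
    services = cbind(c(-0.04, -0.38, 0.10, 0.32), c(-0.23, -0.04, -0.11, 0.38))
  )
}

# class-membership covariate coefficients (class 1 vs reference class 2)
.study_theta_covariates <- c(recent_arrival = 0.93,
                             bachelor_plus = -0.62,
                             clinic_client = -0.88)

.study_class_shares <- c(0.66, 0.34)

# marginal covariate prevalences mirroring the study population mix
.study_covariate_prevalence <- c(recent_arrival = 0.30,
                                 bachelor_plus = 0.68,
                                 clinic_client = 0.86)

# per-class coded coefficient matrix (13 x 2) from the level preset,
# re-centred so each block sums to exactly zero before dropping the
# reference level
.study_class_betas_coded <- function(space = study_attribute_space()) {
  lev <- .study_class_levels()
  out <- NULL
  for (k in names(space$attributes)) {
    M <- lev[[k]]
    M <- sweep(M, 2, colMeans(M))          # exact zero-sum per class
    ref <- space$reference[k]
    keep <- setdiff(seq_len(nrow(M)), ref)
    rownames(M) <- paste0(k, "=", space$attributes[[k]])
    out <- rbind(out, M[keep, , drop = FALSE])
  }
  colnames(out) <- c("class1", "class2")
  out
}

#' Packaged simulation scenarios
#'
#' The three packaged product scenarios used for uptake prediction: the
#' current ("status quo") tool configuration, the best scenario built from
#' the most preferred level of each attribute, and the worst scenario built
#' from the least preferred levels.
#'
#' @return Named list of scenarios (named character vectors over the
#'   attributes of [study_attribute_space()]).
#' @export
study_scenarios <- function() {
  list(
    status_quo = c(cost = "Free", speed = "Instant", accuracy = "70-79%",
                   anonymity = "No login", app_type = "Web",
                   services = "Report only"),
    best = c(cost = "Free", speed = "1-5 min", accuracy = ">90%",
             anonymity = "No login", app_type = "Web",
             services = "Report + Pathology form"),
    worst = c(cost = "$10", speed = "More than 5 min", accuracy = "60-69%",
              anonymity = "Email login", app_type = "Mobile",
              services = "Report + Helpline")
  )
}
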