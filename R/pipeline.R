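#' Run the full DCE analysis pipeline
#'
#' End-to-end driver over the packaged study emulation: build (or accept) a
#' blocked D-efficient design, simulate a synthetic survey from the chosen
#' truth world, fit the conditional logit, the panel mixed logit and the
#' latent-class model, and derive relative importances and scenario
#' uptakes. All artifacts (design CSV/JSON, choice CSV, fit JSON/text
#' reports, importance and uptake tables) are written under `out_dir`.
#'
#' @param out_dir output directory (created if missing), or `NULL` to skip
#'   writing files.
#' @param seed master seed for the simulated survey.
#' @param world truth world, `"lca"` (default) or `"rpl"`.
#' @param n_respondents respondents to simulate (study default 415).
#' @param n_draws Halton draws for the mixed logit (study default 1000).
#' @param n_classes latent classes (study default 2).
#' @param n_starts random starts for the latent-class fit.
#' @param design optional `choice_design`; default [study_design()].
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the design, dataset, summary, the three
#'   fits, the model comparison table, importances and the uptake table.
#' @export
run_dce_pipeline <- function(out_dir = NULL, seed = 1, world = "lca",
                             n_respondents = 415, n_draws = 1000,
                             n_classes = 2, n_starts = 10,
                             design = study_design(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  say("dcekit pipeline: world=", world, " seed=", seed)

  truth <- default_truth(world, design = design,
                         n_respondents = n_respondents, seed = seed)
  say("simulating ", n_respondents, " respondents...")
  dat <- simulate_choices(design, truth)
  smry <- summarize_choices(dat)
  say(sprintf("  %d tasks, opt-out share %.1f%%", smry$n_tasks,
              100 * smry$opt_out_share))

  say("fitting conditional logit...")
  mnl <- fit_mnl(dat)
  say("fitting mixed logit (", n_draws, " Halton draws)...")
  rpl <- fit_rpl(dat, n_draws = n_draws)
  say("fitting ", n_classes, "-class latent-class model...")
  lca <- fit_lca(dat, n_classes = n_classes, n_starts = n_starts,
                 seed = seed)

  cmp <- model_comparison(MNL = mnl, RPL = rpl, LCA = lca)
  imp <- relative_importance(rpl)
  scens <- study_scenarios()
  uptake <- do.call(rbind, lapply(names(scens), function(nm)
    predict_uptake(rpl, scens[[nm]], name = nm)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_design_csv(design, file.path(out_dir, "design.csv"))
    write_design_json(design, file.path(out_dir, "design.json"))
    write_choice_csv(dat, file.path(out_dir, "choices.csv"))
    write_results(mnl, file.path(out_dir, "fit_mnl"))
    write_results(rpl, file.path(out_dir, "fit_rpl"))
    write_results(lca, file.path(out_dir, "fit_lca"))
    utils::write.csv(data.frame(attribute = names(imp),
                                importance_pct = unname(imp)),
                     file.path(out_dir, "importance.csv"), row.names = FALSE)
    utils::write.csv(uptake, file.path(out_dir, "uptake.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(schema = "dcekit/pipeline_summary/1",
                              seed = seed, world = world,
                              n_respondents = smry$n_respondents,
                              n_tasks = smry$n_tasks,
                              opt_out_share = smry$opt_out_share,
                              model_comparison = cmp),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    say("artifacts written to ", out_dir)
  }

  invisible(list(design = design, data = dat, summary = smry,
                 mnl = mnl, rpl = rpl, lca = lca,
                 comparison = cmp, importance = imp, uptake = uptake,
                 truth = truth))
}
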