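#' Predict the complete genotype-by-environment matrix
#'
#' Builds one model over the union of observed cells (training) and all
#' unobserved cells of the genotype-by-environment grid, fits it, and
#' returns observed values merged with predictions as a complete matrix —
#' the gap-filling step behind G-by-E-pattern extraction and
#' enviromically adapted selection.
#'
#' @param pheno observed phenotypes (`genotype`, `environment`, `value`).
#' @param genotypes genotypes to cover (default: those in `pheno`).
#' @param model model name (default `"M_6"`).
#' @param kernels named kernel list for [build_model()].
#' @param use_observed fill cells observed in `pheno` with their observed
#'   value (default) instead of the model prediction.
#' @param nIter,burnIn,seed MCMC settings.
#' @param ... passed to [build_model()].
#' @return genotype-by-environment numeric matrix, complete.
#' @export
predict_ge_matrix <- function(pheno, genotypes = NULL, model = "M_6",
                              kernels = list(), use_observed = TRUE,
                              nIter = 1500, burnIn = 300, seed = 1L, ...) {
  pheno <- dplyr::filter(tibble::as_tibble(pheno), !is.na(.data$value))
  genotypes <- genotypes %||% unique(pheno$genotype)
  envs <- unique(pheno$environment)
  grid <- tidyr::expand_grid(genotype = genotypes, environment = envs)
  grid <- dplyr::left_join(grid,
                           pheno[, c("genotype", "environment", "value")],
                           by = c("genotype", "environment"))
  extra <- dplyr::anti_join(pheno, grid[, c("genotype", "environment")],
                            by = c("genotype", "environment"))
  all_rows <- dplyr::bind_rows(
    dplyr::mutate(grid, .target = TRUE),
    dplyr::mutate(extra[, c("genotype", "environment", "value")],
                  .target = FALSE))
  train_data <- all_rows
  mask <- is.na(train_data$value)
  spec_data <- dplyr::select(train_data, -".target")
  fit <- fit_gibbs(build_model(model, spec_data, kernels = kernels, ...),
                   nIter = nIter, burnIn = burnIn, seed = seed)
  out <- matrix(NA_real_, length(genotypes), length(envs),
                dimnames = list(genotypes, envs))
  target <- dplyr::filter(train_data, .target)
  need_pred <- if (use_observed) is.na(target$value) else
    rep(TRUE, nrow(target))
  if (any(need_pred)) {
    preds <- predict(fit, newdata = target[need_pred, c("genotype",
                                                        "environment")])
    out[cbind(preds$genotype, preds$environment)] <- preds$prediction
  }
  if (use_observed) {
    obs <- target[!is.na(target$value), ]
    out[cbind(obs$genotype, obs$environment)] <- obs$value
  }
  out
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage `%s` failed: %s (earlier artifacts kept).",
                  name, conditionMessage(e)))
  })
}

#' Run the full enviromic prediction pipeline on synthetic data
#'
#' Orchestrates the four analysis pathways over one simulated dataset:
#' (1) genomic deduplication, across-environment BLUEs and five-fold
#' benchmarks of the across-environment models; (2) within-environment
#' model benchmarks under the quadrant cross-validation (cv1-cv4);
#' (3) core-set selection, G-by-E-pattern extraction, environment
#' clustering and environment-variable importance; (4) reference-set
#' curation, enviromically adapted selection and selection gain. Every
#' stage writes CSV/JSON artifacts plus a manifest recording the seed and
#' a config hash, and a failing stage halts with its name while earlier
#' artifacts are preserved.
#'
#' @param config nested list (or path to a YAML file): optional `sim`
#'   (arguments for [sim_config()]), `pathways` (subset of 1:4),
#'   `models` (for pathway 2), `cv` (runs, min_genotypes_per_env),
#'   `mcmc` (nIter, burnIn), `clustering` (k, min_size, nrounds),
#'   `selection` (top_frac, random_frac, overall_top_n, rate),
#'   `seed`.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("envgp_run_")) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("Reading YAML configs requires the yaml package.")
    }
    config <- yaml::read_yaml(config)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  pathways <- config$pathways %||% 1:4
  mcmc <- utils::modifyList(list(nIter = 1500, burnIn = 300), config$mcmc %||% list())
  manifest <- list(seed = seed, config_hash = rlang::hash(config),
                   started = format(Sys.time()), stages = character())
  note <- function(stage) {
    manifest$stages <<- c(manifest$stages, stage)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  cfg <- do.call(sim_config, c(config$sim %||% list(),
                               list(seed = seed)[!("seed" %in%
                                                     names(config$sim))]))
  sim <- pipeline_stage("simulate", {
    pop <- simulate_population(cfg)
    weather <- simulate_environments(cfg)
    ev <- monthly_evs(weather)
    ph <- simulate_phenotypes(pop$markers, ev, cfg, catalog = pop$catalog)
    write_marker_csv(pop$markers, file.path(out_dir, "markers.csv"))
    utils::write.csv(pop$catalog, file.path(out_dir, "catalog.csv"),
                     row.names = FALSE)
    utils::write.csv(ph$pheno, file.path(out_dir, "phenotypes.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(environment = rownames(ev), unclass(ev),
                                check.names = FALSE),
                     file.path(out_dir, "ev_matrix.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(variance_shares = as.list(ph$truth$variance_shares),
           seed = cfg$seed),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE)
    list(pop = pop, ev = ev, pheno = ph$pheno, truth = ph$truth)
  })
  note("simulate")

  kernels <- pipeline_stage("kernels", {
    k <- c(build_grms(sim$pop$markers), build_erms(sim$ev)[1:4])
    for (nm in names(k)) {
      write_kernel_csv(k[[nm]], file.path(out_dir, paste0(nm, ".csv")))
    }
    k
  })
  note("kernels")

  dist_r <- rogers_distance(sim$pop$markers)
  dedup <- deduplicate(dist_r)
  blues <- NULL

  if (1 %in% pathways) {
    pipeline_stage("across_environment", {
      blues <- estimate_blues(sim$pheno, dedup)
      utils::write.csv(blues, file.path(out_dir, "blues.csv"),
                       row.names = FALSE)
      canon <- dplyr::distinct(blues, genotype = .data$canonical_id,
                               value = .data$blue)
      canon$environment <- "across"
      plan <- fivefold_plan(canon$genotype,
                            runs = config$cv$runs %||% 2, seed = seed)
      res <- cv_evaluate(plan, c("GBLUP_D", "E_GBLUP_D"), kernels = kernels,
                         pheno = canon, nIter = mcmc$nIter,
                         burnIn = mcmc$burnIn, seed = seed)
      utils::write.csv(summarise_cv(res),
                       file.path(out_dir, "cv_fivefold.csv"),
                       row.names = FALSE)
    })
    note("across_environment")
  }

  if (2 %in% pathways) {
    pipeline_stage("within_environment", {
      plan <- quadrant_plan(sim$pheno,
                            min_genotypes_per_env =
                              config$cv$min_genotypes_per_env %||% 50,
                            runs = config$cv$runs %||% 2, seed = seed)
      res <- cv_evaluate(plan, config$models %||% c("M_1", "M_2", "M_6"),
                         kernels = kernels, nIter = mcmc$nIter,
                         burnIn = mcmc$burnIn, seed = seed)
      utils::write.csv(summarise_cv(res),
                       file.path(out_dir, "cv_quadrant.csv"),
                       row.names = FALSE)
      cmp <- compare_models(
        dplyr::filter(summarise_cv(res), .data$cell == "cv1"), "M_1")
      utils::write.csv(cmp, file.path(out_dir, "model_comparison_cv1.csv"),
                       row.names = FALSE)
    })
    note("within_environment")
  }

  if (3 %in% pathways) {
    pipeline_stage("gxe_clustering", {
      lines <- dplyr::filter(sim$pop$catalog,
                             .data$material_type == "line")$genotype_id
      core_n <- min(config$clustering$core_n %||% 100, length(lines))
      core <- select_core_set(dist_r[lines, lines], n = core_n)
      full <- predict_ge_matrix(sim$pheno, genotypes = core,
                                kernels = kernels, nIter = mcmc$nIter,
                                burnIn = mcmc$burnIn, seed = seed)
      patt <- extract_gxe_patterns(full)
      cl <- cluster_gxe(patt, k = config$clustering$k %||% "auto",
                        min_size = config$clustering$min_size %||% 3,
                        seed = seed)
      utils::write.csv(cl$assignment, file.path(out_dir, "env_clusters.csv"),
                       row.names = FALSE)
      imp <- ev_importance(sim$ev, cl,
                           nrounds = config$clustering$nrounds %||% 200,
                           n_splits = min(3, min(table(cl$assignment$cluster))),
                           seed = seed)
      utils::write.csv(imp$importance,
                       file.path(out_dir, "ev_importance.csv"),
                       row.names = FALSE)
      tree_ev <- cluster_environments(sim$ev)
      tree_ge <- cluster_environments(as.matrix(dist(t(patt))))
      write_dendrogram_newick(tree_ev, file.path(out_dir, "tree_ev.nwk"))
      write_dendrogram_newick(tree_ge, file.path(out_dir, "tree_gxe.nwk"))
      manifest$cophenetic_correlation <<-
        cophenetic_correlation(tree_ev, tree_ge)
    })
    note("gxe_clustering")
  }

  if (4 %in% pathways) {
    pipeline_stage("selection_gain", {
      if (is.null(blues)) blues <- estimate_blues(sim$pheno, dedup)
      canon <- dplyr::distinct(blues, genotype_id = .data$canonical_id,
                               blue = .data$blue)
      ref <- curate_reference_set(canon,
                                  top_frac = config$selection$top_frac %||% 0.07,
                                  random_frac =
                                    config$selection$random_frac %||% 0.03,
                                  seed = seed)
      preds <- predict_ge_matrix(sim$pheno, genotypes = ref$genotype_id,
                                 kernels = kernels, nIter = mcmc$nIter,
                                 burnIn = mcmc$burnIn, seed = seed)
      rep_ <- selection_gain(preds, ref,
                             overall_top_n =
                               min(config$selection$overall_top_n %||% 50,
                                   nrow(ref) - 1),
                             rate = config$selection$rate %||% 0.32)
      utils::write.csv(rep_$per_environment,
                       file.path(out_dir, "selection_gain.csv"),
                       row.names = FALSE)
      jsonlite::write_json(as.list(rep_$summary),
                           file.path(out_dir, "selection_summary.json"),
                           auto_unbox = TRUE)
    })
    note("selection_gain")
  }

  manifest$finished <- format(Sys.time())
  note("done")
  invisible(manifest)
}
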