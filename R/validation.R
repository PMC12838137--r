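#' Five-fold cross-validation plan over genotypes
#'
#' Random 80:20 partitions of the (deduplicated) genotypes, `folds` folds
#' per run. Genomic duplicates are treated as a single distinct genotype:
#' folds partition canonical ids, so members of a duplicate group always
#' land in the same fold. Results from all folds of a run are stacked
#' before correlation; 10 runs of 5 folds yield 50 model evaluations.
#'
#' @param genotypes character vector of genotype ids.
#' @param dedup optional duplicate map from [deduplicate()].
#' @param runs,folds number of runs and folds.
#' @param seed integer seed.
#' @return a `cv_plan` (scheme `"fivefold"`).
#' @export
fivefold_plan <- function(genotypes, dedup = NULL, runs = 10, folds = 5,
                          seed = 1L) {
  canonical <- unique(apply_dedup(genotypes, dedup))
  if (length(canonical) < folds) abort("Fewer canonical genotypes than folds.")
  set.seed(as.integer(seed))
  run_list <- lapply(seq_len(runs), function(r) {
    shuffled <- sample(canonical)
    split(shuffled, rep_len(seq_len(folds), length(shuffled)))
  })
  structure(list(scheme = "fivefold", runs = run_list, dedup = dedup,
                 seed = seed),
            class = "cv_plan")
}

#' Scenario-based validation plan over experimental series
#'
#' Each split trains on a stack of `scenario` distinct series and tests on
#' one held-out series; all valid (train, test) splits are enumerated, or
#' subsampled to `max_splits` with the seed when combinatorially many.
#'
#' @param series_map tibble (`genotype_id`, `series`) or named vector.
#' @param scenario number of series in the training stack (1..n_series-1).
#' @param seed integer seed.
#' @param max_splits cap on enumerated splits.
#' @return a `cv_plan` (scheme `"scenario"`).
#' @export
scenario_plan <- function(series_map, scenario, seed = 1L, max_splits = 56) {
  if (is.data.frame(series_map)) {
    series_map <- setNames(as.character(series_map$series),
                           series_map$genotype_id)
  }
  series <- sort(unique(series_map))
  if (scenario >= length(series)) {
    abort(sprintf("scenario = %d needs more than %d series.",
                  scenario, scenario))
  }
  set.seed(as.integer(seed))
  splits <- list()
  for (test_s in series) {
    rest <- setdiff(series, test_s)
    combs <- utils::combn(rest, scenario, simplify = FALSE)
    for (cb in combs) {
      splits[[length(splits) + 1L]] <- list(train_series = cb,
                                            test_series = test_s)
    }
  }
  if (length(splits) > max_splits) {
    splits <- splits[sort(sample.int(length(splits), max_splits))]
  }
  structure(list(scheme = "scenario", runs = splits,
                 series_map = series_map, scenario = scenario, seed = seed),
            class = "cv_plan")
}

#' Quadrant cross-validation plan (cv1-cv4)
#'
#' After filtering environments with more than `min_genotypes_per_env`
#' genotypes, each run samples `frac` of the genotypes and `frac` of the
#' environments as "new" (`round(frac * n)`), splitting the observed cells
#' into four quadrants: Q1 known-by-known, Q2 known genotypes in new
#' environments, Q3 new genotypes in known environments, Q4 new-by-new.
#' Training is a `1 - test_frac_q1` sample of Q1; the test sets are the
#' remaining Q1 cells (cv1) and the complete Q2/Q3/Q4 (cv2/cv3/cv4).
#'
#' @param pheno tibble with `genotype`, `environment`, `value`.
#' @param min_genotypes_per_env environment inclusion threshold.
#' @param frac fraction of genotypes/environments flagged new.
#' @param test_frac_q1 fraction of Q1 held out as the cv1 test set.
#' @param runs number of runs.
#' @param seed integer seed.
#' @return a `cv_plan` (scheme `"quadrant"`) carrying the filtered data
#'   and per-run train/test row indices.
#' @export
quadrant_plan <- function(pheno, min_genotypes_per_env = 50, frac = 0.33,
                          test_frac_q1 = 0.20, runs = 50, seed = 1L) {
  pheno <- dplyr::filter(tibble::as_tibble(pheno), !is.na(.data$value))
  env_n <- pheno |>
    dplyr::group_by(.data$environment) |>
    dplyr::summarise(n = dplyr::n_distinct(.data$genotype))
  keep_env <- env_n$environment[env_n$n > min_genotypes_per_env]
  if (length(keep_env) < 3L) {
    abort("Too few environments left after the genotype-count filter.")
  }
  data <- dplyr::filter(pheno, .data$environment %in% keep_env)
  genos <- unique(data$genotype)
  envs <- unique(data$environment)
  set.seed(as.integer(seed))
  run_list <- lapply(seq_len(runs), function(r) {
    new_g <- sample(genos, round(frac * length(genos)))
    new_e <- sample(envs, round(frac * length(envs)))
    g_new <- data$genotype %in% new_g
    e_new <- data$environment %in% new_e
    q1 <- which(!g_new & !e_new)
    q2 <- which(!g_new & e_new)
    q3 <- which(g_new & !e_new)
    q4 <- which(g_new & e_new)
    if (!length(q1) || !length(q2) || !length(q3) || !length(q4)) {
      abort("Empty quadrant; reduce `frac` or the environment filter.")
    }
    test1 <- sample(q1, round(test_frac_q1 * length(q1)))
    list(train = setdiff(q1, test1),
         tests = list(cv1 = test1, cv2 = q2, cv3 = q3, cv4 = q4),
         new_genotypes = new_g, new_environments = new_e)
  })
  structure(list(scheme = "quadrant", runs = run_list, data = data,
                 seed = seed),
            class = "cv_plan")
}

#' Leave-one-environment-out plan
#'
#' One run per environment; a genotype enters the test set of its
#' environment only if it has at least 3 records in the other
#' environments. Environments whose eligible test set is smaller than 3
#' records are reported as ineligible.
#'
#' @param pheno tibble with `genotype`, `environment`, `value`.
#' @return a `cv_plan` (scheme `"loo"`) with per-environment runs and an
#'   `ineligible` attribute.
#' @export
loo_plan <- function(pheno) {
  data <- dplyr::filter(tibble::as_tibble(pheno), !is.na(.data$value))
  envs <- unique(data$environment)
  if (length(envs) < 2L) abort("Need at least 2 environments.")
  counts <- table(data$genotype)
  runs <- list()
  ineligible <- character()
  for (e in envs) {
    in_e <- data$environment == e
    # records of each test genotype available outside e
    n_elsewhere <- counts[data$genotype[in_e]] - 1L
    test <- which(in_e)[n_elsewhere >= 3L]
    if (length(test) >= 3L) {
      runs[[e]] <- list(environment = e, test = test,
                        train = which(!in_e))
    } else {
      ineligible <- c(ineligible, e)
    }
  }
  if (!length(runs)) abort("No eligible environment for leave-one-out.")
  structure(list(scheme = "loo", runs = runs, data = data,
                 ineligible = ineligible),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("<cv_plan %s: %d run(s)>\n", x$scheme, length(x$runs)))
  invisible(x)
}

#' Prediction ability (Pearson r) and RMSE
#'
#' @param pred,obs aligned numeric vectors.
#' @param group optional grouping (e.g. test environment); groups with
#'   fewer than 3 pairs or zero variance are skipped with a message.
#' @return tibble: group, n, r, rmse; the across-group mean is in
#'   `attr(, "mean_r")`.
#' @export
prediction_ability <- function(pred, obs, group = NULL) {
  if (length(pred) != length(obs)) abort("pred/obs length mismatch.")
  group <- if (is.null(group)) rep("all", length(pred)) else as.character(group)
  out <- list()
  for (g in unique(group)) {
    i <- group == g
    if (sum(i) < 3L) {
      inform(sprintf("Group %s skipped: fewer than 3 pairs.", g))
      next
    }
    if (sd(pred[i]) == 0 || sd(obs[i]) == 0) {
      inform(sprintf("Group %s skipped: zero variance.", g))
      next
    }
    out[[g]] <- tibble::tibble(group = g, n = sum(i),
                               r = cor(pred[i], obs[i]),
                               rmse = sqrt(mean((pred[i] - obs[i])^2)))
  }
  res <- dplyr::bind_rows(out)
  attr(res, "mean_r") <- if (nrow(res)) mean(res$r) else NA_real_
  res
}

#' Compare models to a baseline across paired cross-validation runs
#'
#' @param results tibble with columns `model`, `run`, `r` (per-run mean
#'   prediction ability).
#' @param baseline model label to compare against.
#' @param alpha significance threshold for the paired t-test.
#' @return tibble: model, mean_r, pct_diff (mean percent difference vs the
#'   baseline), t, p, significant.
#' @export
compare_models <- function(results, baseline, alpha = 0.05) {
  results <- tibble::as_tibble(results)
  if (!baseline %in% results$model) abort("Baseline model absent from results.")
  base <- dplyr::filter(results, .data$model == baseline) |>
    dplyr::arrange(.data$run)
  out <- list()
  for (mlab in unique(results$model)) {
    cur <- dplyr::filter(results, .data$model == mlab) |>
      dplyr::arrange(.data$run)
    if (!identical(cur$run, base$run)) {
      abort(sprintf("Runs of model %s are not paired with the baseline.", mlab))
    }
    d <- cur$r - base$r
    if (length(d) < 2L) {
      p <- NA_real_
      tstat <- NA_real_
    } else if (sd(d) == 0) {
      p <- if (all(d == 0)) 1 else .Machine$double.eps
      tstat <- if (all(d == 0)) 0 else Inf * sign(mean(d))
    } else {
      tt <- t.test(cur$r, base$r, paired = TRUE)
      p <- tt$p.value
      tstat <- unname(tt$statistic)
    }
    out[[mlab]] <- tibble::tibble(
      model = mlab, mean_r = mean(cur$r),
      pct_diff = 100 * (mean(cur$r) - mean(base$r)) / abs(mean(base$r)),
      t = tstat, p = p,
      significant = mlab != baseline & !is.na(p) & p < alpha)
  }
  dplyr::bind_rows(out)
}

#' Execute a cross-validation plan for one or more models
#'
#' For every run of the plan, withholds the test phenotypes, fits each
#' model on the training rows with kernels built over all rows
#' (whole-kernel conditioning), predicts the withheld rows, and scores
#' prediction ability: per test environment for quadrant/leave-one-out
#' plans (the per-run value is the mean over test environments), stacked
#' within run for five-fold, per split for scenario plans.
#'
#' @param plan a `cv_plan`.
#' @param models character vector of model names for [build_model()].
#' @param kernels named kernel list passed to [build_model()].
#' @param pheno data for fivefold/scenario plans (tibble `genotype`,
#'   `environment`, `value`, and `series` for scenario); quadrant and loo
#'   plans carry their own filtered data.
#' @param nIter,burnIn MCMC settings per fit.
#' @param seed integer seed; each run/model gets a derived child seed.
#' @param ... further arguments for [build_model()] (catalog, gs_params).
#' @return a `cv_result`: tibble with model, run, cell (cv1..cv4, fold or
#'   environment), environment-level r/rmse plus per-run summaries via
#'   [summarise_cv()].
#' @export
cv_evaluate <- function(plan, models, kernels = list(), pheno = NULL,
                        nIter = 1500, burnIn = 300, seed = 1L, ...) {
  stopifnot(inherits(plan, "cv_plan"))
  rows <- list()
  add_row <- function(model, run, cell, scores) {
    if (!nrow(scores)) return()
    rows[[length(rows) + 1L]] <<- dplyr::mutate(scores, model = model,
                                                run = run, cell = cell,
                                                .before = 1)
  }

  fit_predict <- function(model, data, seed_i) {
    spec <- build_model(model, data, kernels = kernels, ...)
    fit <- fit_gibbs(spec, nIter = nIter, burnIn = burnIn, seed = seed_i)
    predict(fit)
  }

  if (plan$scheme == "quadrant") {
    data <- plan$data
    for (run_i in seq_along(plan$runs)) {
      rn <- plan$runs[[run_i]]
      for (model in models) {
        masked <- data
        test_all <- unlist(rn$tests, use.names = FALSE)
        masked$.obs <- masked$value
        masked$value[test_all] <- NA
        masked <- masked[c(rn$train, test_all), ]
        preds <- fit_predict(model, dplyr::select(masked, -".obs"),
                             child_seed(seed, run_i * 131 +
                                          match(model, models)))
        key <- paste(masked$genotype, masked$environment)
        pk <- setNames(preds$prediction,
                       paste(preds$genotype, preds$environment))
        for (cell in names(rn$tests)) {
          idx <- rn$tests[[cell]]
          kk <- paste(data$genotype[idx], data$environment[idx])
          sc <- prediction_ability(pk[kk], data$value[idx],
                                   group = data$environment[idx])
          add_row(model, run_i, cell, sc)
        }
      }
    }
  } else if (plan$scheme == "loo") {
    data <- plan$data
    for (run_i in seq_along(plan$runs)) {
      rn <- plan$runs[[run_i]]
      for (model in models) {
        masked <- data
        masked$value[rn$test] <- NA
        preds <- fit_predict(model, masked,
                             child_seed(seed, run_i * 131 +
                                          match(model, models)))
        pk <- setNames(preds$prediction,
                       paste(preds$genotype, preds$environment))
        kk <- paste(data$genotype[rn$test], data$environment[rn$test])
        sc <- prediction_ability(pk[kk], data$value[rn$test],
                                 group = data$environment[rn$test])
        add_row(model, run_i, rn$environment, sc)
      }
    }
  } else if (plan$scheme == "fivefold") {
    if (is.null(pheno)) abort("fivefold plans need `pheno`.")
    pheno <- tibble::as_tibble(pheno)
    pheno$canonical <- apply_dedup(pheno$genotype, plan$dedup)
    for (run_i in seq_along(plan$runs)) {
      folds <- plan$runs[[run_i]]
      for (model in models) {
        stack_pred <- numeric(0)
        stack_obs <- numeric(0)
        for (f in seq_along(folds)) {
          masked <- pheno
          test_rows <- which(masked$canonical %in% folds[[f]])
          masked$value[test_rows] <- NA
          preds <- fit_predict(model, dplyr::select(masked, -"canonical"),
                               child_seed(seed, run_i * 577 + f * 7 +
                                            match(model, models)))
          key <- paste(masked$genotype[test_rows],
                       masked$environment[test_rows])
          pk <- setNames(preds$prediction,
                         paste(preds$genotype, preds$environment))
          stack_pred <- c(stack_pred, pk[key])
          stack_obs <- c(stack_obs, pheno$value[test_rows])
        }
        add_row(model, run_i, "stacked",
                prediction_ability(stack_pred, stack_obs))
      }
    }
  } else if (plan$scheme == "scenario") {
    if (is.null(pheno)) abort("scenario plans need `pheno` with `series`.")
    pheno <- tibble::as_tibble(pheno)
    if (!"series" %in% names(pheno)) abort("`pheno` needs a `series` column.")
    for (run_i in seq_along(plan$runs)) {
      sp <- plan$runs[[run_i]]
      for (model in models) {
        masked <- dplyr::filter(pheno, .data$series %in%
                                  c(sp$train_series, sp$test_series))
        test_rows <- which(masked$series == sp$test_series)
        obs <- masked$value[test_rows]
        masked$value[test_rows] <- NA
        preds <- fit_predict(model, masked,
                             child_seed(seed, run_i * 131 +
                                          match(model, models)))
        pk <- setNames(preds$prediction,
                       paste(preds$genotype, preds$environment))
        kk <- paste(masked$genotype[test_rows],
                    masked$environment[test_rows])
        add_row(model, run_i, sp$test_series,
                prediction_ability(pk[kk], obs))
      }
    }
  }
  res <- dplyr::bind_rows(rows)
  class(res) <- c("cv_result", class(res))
  res
}

#' Per-run summaries of a cross-validation result
#'
#' @param result a `cv_result` from [cv_evaluate()].
#' @return tibble with one row per (model, run, cell): the mean
#'   per-environment prediction ability and RMSE.
#' @export
summarise_cv <- function(result) {
  dplyr::group_by(result, .data$model, .data$run, .data$cell) |>
    dplyr::summarise(r = mean(.data$r), rmse = mean(.data$rmse),
                     n_groups = dplyr::n(), .groups = "drop")
}
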