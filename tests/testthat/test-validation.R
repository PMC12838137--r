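test_that("five-fold plans partition canonical genotypes", {
  ids <- sprintf("g%03d", 1:100)
  plan <- fivefold_plan(ids, runs = 10, seed = 3)
  expect_length(plan$runs, 10)
  sizes <- lengths(plan$runs[[1]])
  expect_true(all(sizes == 20))
  expect_setequal(unlist(plan$runs[[1]]), ids)
  # 10 runs x 5 folds = 50 evaluations
  expect_equal(sum(lengths(plan$runs)), 50)
  # duplicates stay in the same fold via their canonical id
  dedup <- tibble::tibble(genotype_id = c("g001", "g002"),
                          canonical_id = c("g001", "g001"))
  plan2 <- fivefold_plan(ids, dedup = dedup, runs = 2, seed = 3)
  expect_false(any(vapply(plan2$runs, function(r)
    "g002" %in% unlist(r), logical(1))))
})

test_that("scenario plans enumerate train/test series splits", {
  smap <- setNames(rep(sprintf("Exp_%d", 1:7), each = 10),
                   sprintf("g%03d", 1:70))
  plan1 <- scenario_plan(smap, scenario = 1, seed = 1, max_splits = 100)
  expect_equal(length(plan1$runs), 7 * 6)
  plan6 <- scenario_plan(smap, scenario = 6, seed = 1)
  expect_equal(length(plan6$runs), 7)
  expect_setequal(vapply(plan6$runs, `[[`, "", "test_series"),
                  sprintf("Exp_%d", 1:7))
  expect_error(scenario_plan(smap, scenario = 7), "series")
})

test_that("quadrant plans partition observed cells into train and cv1-cv4", {
  dat <- tiny_dataset()
  plan <- quadrant_plan(dat$pheno, min_genotypes_per_env = 20, runs = 3,
                        seed = 5)
  envs <- unique(plan$data$environment)
  expect_equal(sum(plan$runs[[1]]$new_environments %in% FALSE) >= 0, TRUE)
  for (rn in plan$runs) {
    all_idx <- sort(unname(c(rn$train, unlist(rn$tests))))
    expect_equal(all_idx, seq_len(nrow(plan$data)))
    # a new genotype never appears among training rows
    train_genos <- plan$data$genotype[rn$train]
    q4_genos <- plan$data$genotype[rn$tests$cv4]
    expect_length(intersect(train_genos, q4_genos), 0)
  }
  # round(frac * n) new environments
  n_new <- length(unique(plan$data$environment[
    plan$runs[[1]]$tests$cv2]))
  expect_equal(n_new, round(0.33 * length(envs)))
})

test_that("leave-one-environment-out enforces the 3-record rule", {
  ph <- tidyr::expand_grid(genotype = sprintf("g%02d", 1:12),
                           environment = paste0("e", 1:5))
  ph$value <- rnorm(nrow(ph))
  plan <- loo_plan(ph)
  expect_length(plan$runs, 5)  # balanced data: every environment eligible
  # a genotype seen in only 2 environments is dropped from those test sets
  ph2 <- dplyr::filter(ph, !(genotype == "g01" &
                               environment %in% paste0("e", 3:5)))
  plan2 <- loo_plan(ph2)
  for (e in c("e1", "e2")) {
    test_genos <- ph2$genotype[plan2$runs[[e]]$test]
    expect_false("g01" %in% test_genos)
  }
  expect_error(loo_plan(ph[ph$environment == "e1", ]), "2 environments")
})

test_that("prediction ability matches hand-computed correlation", {
  pred <- c(1, 2, 3, 4, 5)
  obs <- c(1.2, 1.9, 3.4, 3.9, 5.1)
  res <- prediction_ability(pred, obs)
  expect_equal(res$r, cor(pred, obs))
  expect_equal(res$rmse, sqrt(mean((pred - obs)^2)))
  expect_equal(prediction_ability(obs, obs)$r, 1)
  expect_equal(prediction_ability(-obs, obs)$r, -1)
  # degenerate groups are skipped, not zero-filled
  expect_message(
    res2 <- prediction_ability(c(1, 1, 1, 1, 2, 3),
                               c(1, 2, 3, 1, 2, 3),
                               group = rep(c("a", "b"), each = 3)),
    "zero variance")
  expect_equal(res2$group, "b")
})

test_that("compare_models computes paired percent differences", {
  res <- tibble::tibble(model = rep(c("A", "B"), each = 50),
                        run = rep(1:50, 2),
                        r = c(rep(0.4, 50), rep(0.5, 50)))
  cmp <- compare_models(res, "A")
  expect_equal(cmp$pct_diff[cmp$model == "B"], 25)
  expect_true(cmp$significant[cmp$model == "B"])
  expect_equal(cmp$p[cmp$model == "A"], 1)
  expect_false(cmp$significant[cmp$model == "A"])
  # noisy but consistently shifted runs are significant
  set.seed(1)
  res2 <- tibble::tibble(model = rep(c("A", "B"), each = 50),
                         run = rep(1:50, 2),
                         r = c(rnorm(50, 0.4, 0.02), rnorm(50, 0.5, 0.02)))
  expect_true(compare_models(res2, "A")$significant[2])
  expect_error(compare_models(res[c(1:50, 51:99), ], "A"), "paired")
})

test_that("cv_evaluate runs a small quadrant benchmark end to end", {
  dat <- tiny_dataset()
  plan <- quadrant_plan(dat$pheno, min_genotypes_per_env = 20, runs = 2,
                        seed = 9)
  res <- suppressMessages(
    cv_evaluate(plan, c("M_1", "M_2"), kernels = dat$kernels,
                nIter = 800, burnIn = 200, seed = 11))
  s <- summarise_cv(res)
  expect_setequal(unique(s$cell), c("cv1", "cv2", "cv3", "cv4"))
  expect_equal(nrow(s), 2 * 2 * 4)
  expect_true(all(s$r >= -1 & s$r <= 1))
  # genomics buys accuracy for unseen genotypes (cv3): M_2 beats M_1
  m_means <- tapply(s$r[s$cell == "cv3"], s$model[s$cell == "cv3"], mean)
  expect_gt(m_means[["M_2"]], m_means[["M_1"]])
})

test_that("held-out divergent series predicts worse than five-fold", {
  # the relatedness penalty: training on elite series only and testing on
  # the divergent series is harder than random five-fold splits
  cfg <- sim_config(n_lines = 150, n_hybrids = 0, n_markers = 400,
                    n_sites = 3, n_years = 2, duplicate_count = 0,
                    divergent_frac = 0.3, divergence = 0.35, sparsity = 1,
                    seed = 43,
                    variance_shares = c(env = 0.2, a = 0.5, d = 0, aa = 0,
                                        gxe = 0, error = 0.3))
  pop <- simulate_population(cfg)
  ev <- monthly_evs(simulate_environments(cfg))
  sim <- simulate_phenotypes(pop$markers, ev, cfg)
  bl <- estimate_blues(sim$pheno)
  lines_cat <- pop$catalog
  bl$series <- lines_cat$series[match(bl$genotype_id,
                                      lines_cat$genotype_id)]
  pheno_across <- tibble::tibble(genotype = bl$genotype_id,
                                 environment = "across", value = bl$blue,
                                 series = bl$series)
  kern <- build_grms(pop$markers)
  ff <- fivefold_plan(pheno_across$genotype, runs = 2, seed = 7)
  res_ff <- suppressMessages(
    cv_evaluate(ff, "GBLUP_D", kernels = kern, pheno = pheno_across,
                nIter = 800, burnIn = 200, seed = 3))
  div_series <- sprintf("Exp_%d", cfg$n_series)
  sc <- scenario_plan(setNames(bl$series, bl$genotype_id),
                      scenario = cfg$n_series - 1, seed = 7)
  keep <- vapply(sc$runs, function(r) r$test_series == div_series,
                 logical(1))
  sc$runs <- sc$runs[keep]
  res_sc <- suppressMessages(
    cv_evaluate(sc, "GBLUP_D", kernels = kern, pheno = pheno_across,
                nIter = 800, burnIn = 200, seed = 3))
  expect_gt(mean(res_ff$r), mean(res_sc$r))
})
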