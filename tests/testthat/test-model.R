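test_that("build_model assembles the documented term stacks", {
  dat <- tiny_dataset()
  ph <- dat$pheno
  k <- dat$kernels
  m1 <- build_model("M_1", ph)
  expect_equal(vapply(m1$terms, `[[`, "", "name"), c("E_I", "G_I"))
  m5 <- build_model("M_5", ph, kernels = k)
  m6 <- build_model("M_6", ph, kernels = k)
  expect_equal(vapply(m6$terms, `[[`, "", "name"),
               c(vapply(m5$terms, `[[`, "", "name"), "GE_2"))
  m7 <- build_model("M_7", ph, kernels = k)
  expect_setequal(vapply(m7$terms, `[[`, "", "name"),
                  c("S", "Y", "G_a", "G_d", "GY_a", "GS_I", "GE_1"))
  expect_error(build_model("M_3", ph), "ERM_l")
  expect_error(build_model("M_8", ph, kernels = k), "gs_params")
  # M_8 with a parameter kernel replaces the identity genotype-site term
  gs <- simulate_gs_parameters(dat$pop$catalog, unique(ph$site), k = 2,
                               seed = 3)
  names(gs)[1:2] <- c("genotype", "site")
  m8 <- build_model("M_8", ph, kernels = k, gs_params = gs)
  expect_true("GS" %in% vapply(m8$terms, `[[`, "", "name"))
  expect_false("GS_I" %in% vapply(m8$terms, `[[`, "", "name"))
  m8c <- build_model("M_8", ph, kernels = k, gs_params = gs,
                     gs_mode = "covariate")
  expect_true("GS_I" %in% vapply(m8c$terms, `[[`, "", "name"))
  expect_gt(ncol(m8c$X), 1)
})

test_that("Gibbs posterior means match the closed-form BLUP oracle", {
  dat <- tiny_dataset()
  set.seed(8)
  sub <- dat$pheno[sample(nrow(dat$pheno), 45), ]
  spec <- build_model("M_3", sub, kernels = dat$kernels)
  vars <- list(E_l = 8, G_a = 12, G_d = 2, G_aa = 4, error = 10)
  oracle <- blup_oracle(spec, vars)
  fit <- fit_gibbs(spec, nIter = 6000, burnIn = 1000, seed = 2,
                   fix_variances = vars)
  for (t in names(oracle$effects)) {
    rms <- sqrt(mean((oracle$effects[[t]] - fit$effects[[t]])^2))
    expect_lt(rms, 0.02 * sd(sub$value))
  }
  expect_lt(abs(oracle$fixed[1] - fit$fixed[1]), 0.02 * sd(sub$value))
})

test_that("balanced identity-kernel BLUP equals shrunken genotype means", {
  # 3 genotypes x 4 replicates, identity kernel: u = shrinkage * centered mean
  set.seed(5)
  ph <- tidyr::expand_grid(genotype = c("g1", "g2", "g3"),
                           environment = paste0("e", 1:4))
  ph$value <- rnorm(12, mean = rep(c(10, 12, 14), each = 4))
  term <- list(name = "G", kernel = identity_kernel(c("g1", "g2", "g3")),
               levels = ph$genotype, level_cols = "genotype")
  spec <- envgp:::new_kmm_spec("toy", ph, ~1, list(term))
  vars <- list(G = 4, error = 2)
  fit <- blup_oracle(spec, vars)
  gm <- as.vector(tapply(ph$value, ph$genotype, mean))
  shrink <- 4 / (4 + 2 / 4)  # s2_g / (s2_g + s2_e / n_rep)
  expect_equal(unname(fit$effects$G),
               shrink * (gm - mean(ph$value)), tolerance = 1e-6)
})

test_that("the oracle approaches per-genotype fixed effects as s2_g grows", {
  ph <- tidyr::expand_grid(genotype = c("g1", "g2"),
                           environment = paste0("e", 1:3))
  ph$value <- c(10, 10, 10, 20, 20, 20)
  term <- list(name = "G", kernel = identity_kernel(c("g1", "g2")),
               levels = ph$genotype, level_cols = "genotype")
  spec <- envgp:::new_kmm_spec("toy", ph, ~1, list(term))
  fit <- blup_oracle(spec, list(G = 1e8, error = 1))
  expect_equal(unname(fit$effects$G), c(-5, 5), tolerance = 1e-3)
  # duplicated data rows leave the solution unchanged
  ph2 <- dplyr::bind_rows(ph, ph)
  term2 <- list(name = "G", kernel = identity_kernel(c("g1", "g2")),
                levels = ph2$genotype, level_cols = "genotype")
  spec2 <- envgp:::new_kmm_spec("toy", ph2, ~1, list(term2))
  fit2 <- blup_oracle(spec2, list(G = 4, error = 2))
  fit1 <- blup_oracle(spec, list(G = 4, error = 1))  # duplication halves s2_e
  expect_equal(fit2$effects$G, fit1$effects$G, tolerance = 1e-8)
})

test_that("degenerate and invalid fits fail or collapse cleanly", {
  dat <- tiny_dataset()
  sub <- dat$pheno[1:40, ]
  spec <- build_model("M_1", sub)
  expect_error(fit_gibbs(spec, nIter = 100, burnIn = 200), "exceed")
  sub2 <- sub
  sub2$value <- 5
  spec2 <- build_model("M_1", sub2)
  fit2 <- fit_gibbs(spec2, nIter = 800, burnIn = 200, seed = 1)
  expect_lt(sum(fit2$var_components$mean), 1e-3)
  sub3 <- sub
  sub3$value[1] <- Inf
  expect_error(fit_gibbs(build_model("M_1", sub3), seed = 1), "finite")
})

test_that("predictions condition on the whole kernel", {
  dat <- tiny_dataset()
  ph <- dat$pheno
  # hold out one genotype entirely
  gid <- ph$genotype[1]
  ph$value[ph$genotype == gid] <- NA
  fit1 <- fit_gibbs(build_model("M_1", ph), nIter = 1500, burnIn = 300,
                    seed = 3)
  p1 <- predict(fit1)
  # under M_1 an unseen genotype's prediction is intercept + environment
  # effect plus only Monte-Carlo prior noise
  e_eff <- fit1$effects$E_I[p1$environment]
  noise <- p1$prediction - fit1$fixed[1] - e_eff
  expect_lt(max(abs(noise)), 1.5)
  expect_lt(abs(mean(noise)), 0.75)
  # a genomically linked duplicate inherits its twin's genetic value
  dup <- grep("_dup$", unique(dat$pheno$genotype), value = TRUE)[1]
  src <- sub("_dup$", "", dup)
  ph2 <- dat$pheno
  ph2$value[ph2$genotype == dup] <- NA
  fit2 <- fit_gibbs(build_model("M_2", ph2, kernels = dat$kernels),
                    nIter = 1500, burnIn = 300, seed = 3)
  expect_equal(fit2$effects$G_a[dup], fit2$effects$G_a[src],
               tolerance = 0.15, ignore_attr = TRUE)
  expect_error(predict(fit2, newdata = tibble::tibble(
    genotype = "nobody", environment = ph2$environment[1])), "absent")
})

test_that("prediction is invariant to training row order", {
  dat <- tiny_dataset()
  ph <- dat$pheno
  ph$value[1:30] <- NA
  fit_a <- fit_gibbs(build_model("M_2", ph, kernels = dat$kernels),
                     nIter = 1200, burnIn = 300, seed = 5)
  perm <- c(1:30, 30 + sample(nrow(ph) - 30))
  fit_b <- fit_gibbs(build_model("M_2", ph[perm, ], kernels = dat$kernels),
                     nIter = 1200, burnIn = 300, seed = 5)
  pa <- predict(fit_a)
  pb <- predict(fit_b)
  key <- paste(pa$genotype, pa$environment)
  pb_v <- setNames(pb$prediction, paste(pb$genotype, pb$environment))[key]
  expect_gt(cor(pa$prediction, pb_v), 0.98)
})

test_that("structured models reduce to the baseline under identity kernels", {
  dat <- tiny_dataset()
  ph <- dat$pheno[1:150, ]
  genos <- unique(ph$genotype)
  envs <- unique(ph$environment)
  id_kernels <- list(GRM_a = identity_kernel(genos),
                     GRM_d = identity_kernel(genos),
                     GRM_aa = identity_kernel(genos),
                     ERM_l = identity_kernel(envs),
                     ERM_nl = identity_kernel(envs))
  # the identity kernels are structurally identity but carry kind labels,
  # so M_2 takes the dense path; fitted values must match M_1
  for (k in names(id_kernels)) attr(id_kernels[[k]], "kind") <- k
  fit_m1 <- fit_gibbs(build_model("M_1", ph), nIter = 2500, burnIn = 500,
                      seed = 7)
  fit_m3 <- fit_gibbs(build_model("M_3", ph, kernels = id_kernels),
                      nIter = 2500, burnIn = 500, seed = 7)
  expect_gt(cor(fit_m1$fitted$fitted, fit_m3$fitted$fitted), 0.98)
})

test_that("variance decomposition recovers heritability structure", {
  cfg <- sim_config(n_lines = 120, n_hybrids = 60, n_markers = 300,
                    n_sites = 4, n_years = 2, duplicate_count = 0,
                    sparsity = 0.8, seed = 29,
                    variance_shares = c(env = 0.25, a = 0.35, d = 0.05,
                                        aa = 0.10, gxe = 0.10,
                                        error = 0.15))
  pop <- simulate_population(cfg)
  ev <- monthly_evs(simulate_environments(cfg))
  sim <- simulate_phenotypes(pop$markers, ev, cfg, catalog = pop$catalog)
  dec <- variance_decomposition_h2(sim$pheno, pop$catalog,
                                   nIter = 1500, burnIn = 300, seed = 2)
  expect_setequal(dec$h2$group, c("line", "hybrid"))
  expect_true(all(dec$h2$H2 > 0.5 & dec$h2$H2 <= 1))
  # permuting genotype labels destroys the line variance
  ph_perm <- sim$pheno
  set.seed(1)
  ph_perm$value <- sample(ph_perm$value)
  dec_p <- variance_decomposition_h2(ph_perm, pop$catalog,
                                     nIter = 1000, burnIn = 200, seed = 2)
  vc <- setNames(dec_p$var_components$mean, dec_p$var_components$term)
  total <- sum(vc)
  expect_lt(vc[["Line"]] / total, 0.05)
  # a hybrid without parents errors
  bad_cat <- pop$catalog
  bad_cat$female_parent[bad_cat$material_type == "hybrid"][1] <- NA
  expect_error(variance_decomposition_h2(sim$pheno, bad_cat, nIter = 500,
                                         burnIn = 100), "parent")
})

test_that("genomic repeatability separates signal from noise", {
  cfg <- sim_config(n_lines = 150, n_hybrids = 0, n_markers = 300,
                    n_sites = 1, n_years = 1, duplicate_count = 0,
                    sparsity = 1, seed = 37,
                    variance_shares = c(env = 0, a = 0.9, d = 0, aa = 0,
                                        gxe = 0, error = 0.1))
  pop <- simulate_population(cfg)
  ev <- monthly_evs(simulate_environments(cfg))
  sim <- simulate_phenotypes(pop$markers, ev, cfg)
  grm <- build_grms(pop$markers)$GRM_a
  rep_hi <- genomic_repeatability(sim$pheno, grm, seed = 4)
  expect_gt(rep_hi$repeatability[1], 0.7)
  # pure noise trait: the scaled-inverse-chi-square prior keeps a floor
  # under the genomic share when n equals the number of genotypes, so the
  # null level (derived by simulation) is well below the signal level but
  # not zero
  ph0 <- sim$pheno
  set.seed(2)
  ph0$value <- rnorm(nrow(ph0))
  rep_lo <- genomic_repeatability(ph0, grm, seed = 4)
  expect_lt(rep_lo$repeatability[1], 0.45)
  expect_gt(rep_hi$repeatability[1] - rep_lo$repeatability[1], 0.25)
  expect_true(all(rep_lo$repeatability >= 0 & rep_lo$repeatability <= 1))
  # environments below the genotype threshold are skipped with a warning
  ph_mix <- dplyr::bind_rows(
    sim$pheno,
    dplyr::mutate(sim$pheno[1:10, ], environment = "tiny_env"))
  expect_warning(
    rep_mix <- genomic_repeatability(ph_mix, grm, min_genotypes = 30,
                                     nIter = 600, burnIn = 150, seed = 1),
    "skipped")
  expect_false("tiny_env" %in% rep_mix$environment)
})

test_that("BLUEs absorb environment effects and merge duplicates", {
  # balanced 2-environment toy with a +10 environment shift
  ph <- tidyr::expand_grid(genotype = c("g1", "g2", "g3", "g4"),
                           environment = c("e1", "e2"))
  gm <- c(g1 = 1, g2 = 2, g3 = 3, g4 = 4)
  ph$value <- gm[ph$genotype] + ifelse(ph$environment == "e2", 10, 0)
  bl <- estimate_blues(ph)
  est <- setNames(bl$blue, bl$genotype_id)
  expect_equal(unname(diff(est[c("g1", "g4")])), 3, tolerance = 1e-6)
  # duplicates collapse to identical BLUEs mapped back to members
  dedup <- tibble::tibble(genotype_id = c("g1", "g2", "g3", "g4"),
                          canonical_id = c("g1", "g1", "g3", "g4"))
  bl2 <- estimate_blues(ph, dedup)
  est2 <- setNames(bl2$blue, bl2$genotype_id)
  expect_equal(est2[["g1"]], est2[["g2"]])
  # single environment: centered genotype means
  ph1 <- dplyr::filter(ph, environment == "e1")
  bl1 <- estimate_blues(ph1)
  expect_equal(setNames(bl1$blue, bl1$genotype_id)[c("g1", "g4")],
               gm[c("g1", "g4")], ignore_attr = TRUE)
  # a disconnected incidence graph errors
  ph_disc <- tibble::tibble(
    genotype = c("a", "a", "b", "c", "c", "d"),
    environment = c("e1", "e2", "e1", "e3", "e4", "e3"),
    value = rnorm(6))
  expect_error(estimate_blues(ph_disc), "disconnected")
})
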