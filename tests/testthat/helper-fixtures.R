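# Small shared fixtures, generated in code. Heavier objects are memoised per
# session so several test files can reuse them.

tiny_cfg <- function(seed = 7, sparsity = 0.8, ...) {
  sim_config(n_lines = 60, n_hybrids = 30, n_markers = 250,
             n_chromosomes = 3, n_sites = 3, n_years = 2,
             duplicate_count = 3, sparsity = sparsity, seed = seed, ...)
}

# 24 environments (6 sites x 4 years) for classifier-scale tests, memoised
medium_ev <- function() {
  if (is.null(.fixture_env$medium_ev)) {
    cfg <- sim_config(n_lines = 10, n_hybrids = 0, n_markers = 50,
                      n_sites = 6, n_years = 4, duplicate_count = 0,
                      seed = 77)
    .fixture_env$medium_ev <- monthly_evs(simulate_environments(cfg))
  }
  .fixture_env$medium_ev
}

.fixture_env <- new.env(parent = emptyenv())

tiny_dataset <- function() {
  if (is.null(.fixture_env$tiny)) {
    cfg <- tiny_cfg()
    pop <- simulate_population(cfg)
    weather <- simulate_environments(cfg)
    ev <- monthly_evs(weather)
    ph <- simulate_phenotypes(pop$markers, ev, cfg, catalog = pop$catalog)
    kernels <- c(build_grms(pop$markers), build_erms(ev)[1:4])
    .fixture_env$tiny <- list(cfg = cfg, pop = pop, weather = weather,
                              ev = ev, pheno = ph$pheno, truth = ph$truth,
                              kernels = kernels)
  }
  .fixture_env$tiny
}

subset_genotypes_for_test <- function(m, ids) {
  marker_set(m$codes[ids, , drop = FALSE], m$map)
}

# hand-coded 4 genotypes x 5 markers with one rare and one monomorphic marker
toy_markers <- function() {
  codes <- rbind(
    g1 = c(0, 2, 1, 0, 0),
    g2 = c(2, 2, 1, 0, 0),
    g3 = c(0, 0, 2, 0, 0),
    g4 = c(2, 2, 0, 0, 2))
  colnames(codes) <- paste0("m", 1:5)
  marker_set(codes, tibble::tibble(marker_id = paste0("m", 1:5),
                                   chrom = "chr1",
                                   pos = c(10L, 100L, 1000L, 5000L, 9000L)))
}

# brute-force Weir-Cockerham single-marker Fst oracle (two groups)
wc_fst_oracle <- function(codes1, codes2) {
  n1 <- nrow(codes1); n2 <- nrow(codes2)
  p1 <- colMeans(codes1) / 2; p2 <- colMeans(codes2) / 2
  h1 <- colMeans(codes1 == 1); h2 <- colMeans(codes2 == 1)
  nbar <- (n1 + n2) / 2
  nc <- (2 * nbar - (n1^2 + n2^2) / (2 * nbar))
  pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  sum(a) / sum(a + b + cc)
}

# adjusted Rand index between two partitions (independent of cluster_gxe)
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(a, b))
  }
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_ <- sum_a * sum_b / n
  (sum_ij - exp_) / ((sum_a + sum_b) / 2 - exp_)
}
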