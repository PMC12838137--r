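#' Across-environment BLUEs with genomic deduplication
#'
#' Fits the integration model `value = mu + genotype (fixed) + environment
#' (random) + error`. Genomic duplicates are collapsed to their canonical
#' id before fitting — this is what connects otherwise disjoint trial
#' series — and the resulting estimates are mapped back to every member
#' id. With a single environment the BLUEs are the within-environment
#' genotype means.
#'
#' @param pheno tibble with `genotype`, `environment`, `value`.
#' @param dedup optional duplicate map from [deduplicate()].
#' @return tibble `genotype_id`, `canonical_id`, `blue`.
#' @export
estimate_blues <- function(pheno, dedup = NULL) {
  pheno <- tibble::as_tibble(pheno)
  pheno$canonical <- apply_dedup(pheno$genotype, dedup)
  pheno <- dplyr::filter(pheno, !is.na(.data$value))

  # connectivity of the genotype-environment incidence graph
  edges <- dplyr::distinct(pheno, .data$canonical, .data$environment)
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0("G|", edges$canonical),
               to = paste0("E|", edges$environment)), directed = FALSE)
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    sizes <- paste(comp$csize, collapse = ", ")
    abort(sprintf(paste0("Genotype-environment incidence graph is ",
                         "disconnected (%d components of sizes %s); ",
                         "BLUEs are not comparable across components."),
                  comp$no, sizes))
  }

  n_env <- length(unique(pheno$environment))
  if (n_env == 1L) {
    est <- pheno |>
      dplyr::group_by(canonical_id = .data$canonical) |>
      dplyr::summarise(blue = mean(.data$value), .groups = "drop")
  } else {
    fit <- lme4::lmer(value ~ 0 + canonical + (1 | environment),
                      data = pheno,
                      control = lme4::lmerControl(calc.derivs = FALSE))
    fe <- lme4::fixef(fit)
    est <- tibble::tibble(canonical_id = sub("^canonical", "", names(fe)),
                          blue = unname(fe))
  }

  members <- tibble::tibble(genotype_id = unique(pheno$genotype))
  members$canonical_id <- apply_dedup(members$genotype_id, dedup)
  if (!is.null(dedup)) {
    extra <- dedup[dedup$canonical_id %in% est$canonical_id &
                     !(dedup$genotype_id %in% members$genotype_id), ]
    members <- dplyr::bind_rows(members, extra)
  }
  dplyr::inner_join(members, est, by = "canonical_id")
}

#' Variance decomposition and broad-sense heritability
#'
#' Fits the integrated variance-decomposition model: material type and
#' series fixed; environment, line main effects, hybrid general (female and
#' male parent) and specific combining abilities, and all their
#' environment interactions random with identity covariances; residual
#' variances heterogeneous per environment. Entry-mean broad-sense
#' heritabilities use the harmonic mean number of environments per
#' genotype:
#' `H2 = s2_G / (s2_G + s2_GxE / nbar + s2_e / nbar)`,
#' with `s2_G = s2_Line` for lines and `s2_GCA_F + s2_GCA_M + s2_SCA` for
#' hybrids (interaction terms summed analogously).
#'
#' @param pheno tibble with `genotype`, `environment`, `value`.
#' @param catalog genotype catalog resolving `material_type` and parents.
#' @param nIter,burnIn,seed MCMC settings passed to [fit_gibbs()].
#' @return list: `h2` (tibble group, n_genotypes, n_bar_env, H2),
#'   `var_components`, and the underlying `fit`.
#' @export
variance_decomposition_h2 <- function(pheno, catalog, nIter = 3000,
                                      burnIn = 500, seed = 1L) {
  pheno <- tibble::as_tibble(pheno)
  pheno$genotype <- as.character(pheno$genotype)
  cat_i <- match(pheno$genotype, catalog$genotype_id)
  if (anyNA(cat_i)) abort("Catalog does not cover all phenotyped genotypes.")
  pheno$type <- catalog$material_type[cat_i]
  pheno$series <- as.character(catalog$series[cat_i])
  pheno$female <- catalog$female_parent[cat_i]
  pheno$male <- catalog$male_parent[cat_i]
  is_hyb <- pheno$type == "hybrid"
  if (any(is_hyb & (is.na(pheno$female) | is.na(pheno$male)))) {
    bad <- unique(pheno$genotype[is_hyb &
                                   (is.na(pheno$female) | is.na(pheno$male))])
    abort(sprintf("Hybrid(s) lacking parent ids: %s",
                  paste(head(bad, 5), collapse = ", ")))
  }

  fx <- c()
  if (length(unique(pheno$type)) > 1L) fx <- c(fx, "type")
  if (length(unique(pheno$series)) > 1L) fx <- c(fx, "series")
  fixed_formula <- stats::as.formula(
    paste("~", if (length(fx)) paste(fx, collapse = " + ") else "1"))

  lv <- function(x, mask = NULL) {
    x <- as.character(x)
    if (!is.null(mask)) x[!mask] <- NA_character_
    x
  }
  id_term <- function(nm, levels) {
    labels <- unique(levels[!is.na(levels)])
    list(name = nm, kernel = identity_kernel(labels), levels = levels,
         level_cols = NULL)
  }
  env <- pheno$environment
  terms <- list(id_term("Env", lv(env)))
  has_lines <- any(!is_hyb)
  if (has_lines) {
    terms <- c(terms,
               list(id_term("Line", lv(pheno$genotype, !is_hyb)),
                    id_term("Env:Line", lv(paste(env, pheno$genotype,
                                                 sep = ":"), !is_hyb))))
  }
  if (any(is_hyb)) {
    terms <- c(terms, list(
      id_term("GCA_F", lv(pheno$female, is_hyb)),
      id_term("GCA_M", lv(pheno$male, is_hyb)),
      id_term("SCA", lv(pheno$genotype, is_hyb)),
      id_term("Env:GCA_F", lv(paste(env, pheno$female, sep = ":"), is_hyb)),
      id_term("Env:GCA_M", lv(paste(env, pheno$male, sep = ":"), is_hyb)),
      id_term("Env:SCA", lv(paste(env, pheno$genotype, sep = ":"), is_hyb))))
  }

  spec <- new_kmm_spec("H2", pheno, fixed_formula, terms)
  spec <- with_residual_groups(spec, pheno$environment)
  fit <- fit_gibbs(spec, nIter = nIter, burnIn = burnIn, seed = seed)

  vc <- setNames(fit$var_components$mean, fit$var_components$term)
  s2e_bar <- mean(vc[grepl("^error@", names(vc))])
  harm <- function(x) length(x) / sum(1 / x)
  h2_rows <- list()
  if (has_lines) {
    envs_per <- table(pheno$genotype[!is_hyb])
    envs_per <- tapply(pheno$environment[!is_hyb], pheno$genotype[!is_hyb],
                       function(e) length(unique(e)))
    nbar <- harm(envs_per)
    h2 <- vc[["Line"]] /
      (vc[["Line"]] + vc[["Env:Line"]] / nbar + s2e_bar / nbar)
    h2_rows$line <- tibble::tibble(group = "line",
                                   n_genotypes = length(envs_per),
                                   n_bar_env = nbar, H2 = h2)
  }
  if (any(is_hyb)) {
    envs_per <- tapply(pheno$environment[is_hyb], pheno$genotype[is_hyb],
                       function(e) length(unique(e)))
    nbar <- harm(envs_per)
    s2g <- vc[["GCA_F"]] + vc[["GCA_M"]] + vc[["SCA"]]
    s2ge <- vc[["Env:GCA_F"]] + vc[["Env:GCA_M"]] + vc[["Env:SCA"]]
    h2 <- s2g / (s2g + s2ge / nbar + s2e_bar / nbar)
    h2_rows$hybrid <- tibble::tibble(group = "hybrid",
                                     n_genotypes = length(envs_per),
                                     n_bar_env = nbar, H2 = h2)
  }
  list(h2 = dplyr::bind_rows(h2_rows), var_components = fit$var_components,
       fit = fit)
}

#' Per-environment genomic repeatability
#'
#' Within each environment fits `value = mu + g_a + e` with the additive
#' genomic kernel and reports the within-environment ratio of genomic to
#' total variance on the phenotypic scale,
#' `s2_a dbar / (s2_a dbar + s2_e)`, where `dbar` is the mean kernel
#' diagonal of the fitted genotypes (about 2 for a VanRaden kernel over
#' fully inbred lines), so the ratio is comparable across marker codings.
#'
#' @param pheno tibble with `genotype`, `environment`, `value` (or a
#'   genotype-by-site parameter response reshaped to the same columns).
#' @param grm_a additive genomic kernel covering the genotypes.
#' @param min_genotypes environments with fewer genotypes are skipped with
#'   a warning.
#' @param nIter,burnIn,seed MCMC settings.
#' @return tibble: environment, n, repeatability.
#' @export
genomic_repeatability <- function(pheno, grm_a, min_genotypes = 30,
                                  nIter = 2000, burnIn = 400, seed = 1L) {
  pheno <- tibble::as_tibble(pheno)
  out <- list()
  for (e in unique(pheno$environment)) {
    sub <- dplyr::filter(pheno, .data$environment == e, !is.na(.data$value))
    if (nrow(sub) < min_genotypes) {
      warn(sprintf("Environment %s skipped: %d genotypes < %d.",
                   e, nrow(sub), min_genotypes))
      next
    }
    genos <- unique(sub$genotype)
    k_sub <- new_kernel(unclass(grm_a)[genos, genos, drop = FALSE], "GRM_a")
    term <- list(name = "G_a", kernel = k_sub, levels = sub$genotype,
                 level_cols = "genotype")
    spec <- new_kmm_spec("GBLUP", sub, ~1, list(term))
    fit <- fit_gibbs(spec, nIter = nIter, burnIn = burnIn,
                     seed = child_seed(seed, match(e, unique(pheno$environment))))
    vc <- setNames(fit$var_components$mean, fit$var_components$term)
    dbar <- mean(diag(unclass(k_sub)))
    out[[e]] <- tibble::tibble(environment = e, n = nrow(sub),
                               repeatability = vc[["G_a"]] * dbar /
                                 (vc[["G_a"]] * dbar + vc[["error"]]))
  }
  if (!length(out)) abort("No environment had enough genotypes.")
  dplyr::bind_rows(out)
}
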