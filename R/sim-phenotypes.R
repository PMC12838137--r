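#' Simulate multi-environment phenotypes with kernel-structured effects
#'
#' Draws every effect vector from the same kernel-structured normal
#' distributions the prediction models assume:
#' `y = mu + u_env + u_a + u_d + u_aa + u_gxe (+ u_gy + u_gs) + e`, with
#' `u_a ~ N(0, GRM_a s2)` etc., the environment effect drawn from `ERM_nl`
#' and the G-by-E effect from the Kronecker structure of `GRM_a` and
#' `ERM_nl` (Cholesky with 1e-8 diagonal jitter). Each component is
#' rescaled to its exact configured share of the total phenotypic variance
#' (empirical standardization over the full genotype-by-environment grid),
#' so the returned truth record makes recovery tests well-posed. Observed
#' cells are then subsampled to `cfg$sparsity`.
#'
#' @param markers a [marker_set()] (complete codes).
#' @param ev an `ev_matrix` from [monthly_evs()].
#' @param cfg a [sim_config()]; `cfg$variance_shares` must name `env`,
#'   `a`, `d`, `aa`, `gxe`, `error` (optional extras `gy`, `gs`).
#' @param catalog optional genotype catalog; adds `series`/`type` columns.
#' @return list with `pheno` (tibble: genotype, environment, site, year,
#'   value, plus catalog columns) and `truth` (a `truth_record`: the
#'   variance shares, per-term effect vectors/matrices, and the seed).
#' @export
simulate_phenotypes <- function(markers, ev, cfg, catalog = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  shares <- cfg$variance_shares
  required <- c("env", "a", "d", "aa", "gxe", "error")
  missing <- setdiff(required, names(shares))
  if (length(missing)) {
    abort(sprintf("variance_shares missing required term(s): %s",
                  paste(missing, collapse = ", ")))
  }
  set.seed(child_seed(cfg$seed, 3L))

  grms <- build_grms(markers)
  genos <- genotype_ids(markers)
  envs <- rownames(ev)
  n_g <- length(genos)
  n_e <- length(envs)
  total_var <- cfg$total_var
  if (n_e < 2L) {
    if (shares[["env"]] > 0 || shares[["gxe"]] > 0) {
      abort("env and gxe shares must be 0 with a single environment.")
    }
    erms <- NULL
  } else {
    erms <- build_erms(ev)
  }

  chol_jitter <- function(k) {
    m <- unclass(k)
    t(chol(m + diag(1e-8 * mean(diag(m)) + 1e-12, nrow(m))))
  }
  draw_kernel <- function(k) as.vector(chol_jitter(k) %*% rnorm(nrow(k)))
  # rescale a grid-expanded component to its exact variance share
  rescale <- function(x, share) {
    if (share == 0) return(x * 0)
    s <- sd(as.vector(x))
    if (s == 0) return(x)
    x / s * sqrt(share * total_var)
  }

  L_g <- chol_jitter(grms$GRM_a)
  L_e <- if (!is.null(erms)) chol_jitter(erms$ERM_nl) else
    matrix(0, n_e, n_e)

  u_env <- if (!is.null(erms)) {
    rescale(draw_kernel(erms$ERM_nl), shares[["env"]])
  } else rep(0, n_e)
  # genotype main effects vary only across genotypes; their grid variance
  # equals their genotype-level variance in a balanced grid
  u_a <- rescale(draw_kernel(grms$GRM_a), shares[["a"]])
  u_d <- rescale(draw_kernel(grms$GRM_d), shares[["d"]])
  u_aa <- rescale(draw_kernel(grms$GRM_aa), shares[["aa"]])
  u_ge <- rescale(L_g %*% matrix(rnorm(n_g * n_e), n_g) %*% t(L_e),
                  shares[["gxe"]])
  dimnames(u_ge) <- list(genos, envs)

  info <- attr(ev, "env_info")
  effects <- list(env = setNames(u_env, envs), a = setNames(u_a, genos),
                  d = setNames(u_d, genos), aa = setNames(u_aa, genos),
                  gxe = u_ge)

  grid <- tidyr::expand_grid(genotype = genos, environment = envs)
  gi <- match(grid$genotype, genos)
  ei <- match(grid$environment, envs)
  value <- cfg$mu + u_env[ei] + u_a[gi] + u_d[gi] + u_aa[gi] +
    u_ge[cbind(gi, ei)]

  if ("gy" %in% names(shares) && shares[["gy"]] > 0) {
    yr <- as.character(info$year[match(envs, info$environment)])
    L_y <- chol_jitter(erms$YRM)
    u_gy <- L_g %*% matrix(rnorm(n_g * nrow(erms$YRM)), n_g) %*% t(L_y)
    dimnames(u_gy) <- list(genos, rownames(erms$YRM))
    u_gy <- rescale(u_gy[, yr[ei], drop = FALSE][cbind(gi, seq_along(ei))],
                    shares[["gy"]])
    value <- value + u_gy
    effects$gy <- u_gy
  }
  if ("gs" %in% names(shares) && shares[["gs"]] > 0) {
    st <- as.character(info$site[match(envs, info$environment)])
    u_gs_mat <- matrix(rnorm(n_g * length(unique(st))), n_g,
                       dimnames = list(genos, unique(st)))
    u_gs <- rescale(u_gs_mat[cbind(gi, match(st[ei], colnames(u_gs_mat)))],
                    shares[["gs"]])
    value <- value + u_gs
    effects$gs <- u_gs
  }

  noise <- rescale(rnorm(nrow(grid)), shares[["error"]])
  value <- value + noise

  grid$site <- as.character(info$site[match(grid$environment, info$environment)])
  grid$year <- as.character(info$year[match(grid$environment, info$environment)])
  grid$value <- as.vector(value)

  n_obs <- round(cfg$sparsity * nrow(grid))
  keep <- sort(sample.int(nrow(grid), n_obs))
  pheno <- grid[keep, ]

  if (!is.null(catalog)) {
    i <- match(pheno$genotype, catalog$genotype_id)
    pheno$series <- catalog$series[i]
    pheno$type <- catalog$material_type[i]
  }

  truth <- structure(list(variance_shares = shares, true_effects = effects,
                          mu = cfg$mu, total_var = total_var,
                          seed = cfg$seed),
                     class = "truth_record")
  list(pheno = pheno, truth = truth)
}

#' @export
print.truth_record <- function(x, ...) {
  cat("<truth_record: shares",
      paste(sprintf("%s=%.2f", names(x$variance_shares), x$variance_shares),
            collapse = ", "),
      sprintf("(seed %d)>\n", x$seed))
  invisible(x)
}

#' Simulate crop-growth-model genotype-by-site parameters
#'
#' Stand-in for process-based crop-growth-model calibration output: one row
#' per genotype-by-site combination with `k` correlated parameters, each
#' composed of a genomically structured genotype component (variance
#' `heritable_frac`), a site component, and genotype-site
#' interaction-plus-noise (variance `1 - heritable_frac`), so the per-site
#' genomic repeatability of each parameter is approximately
#' `heritable_frac`.
#'
#' @param catalog genotype catalog (all its genotypes get rows).
#' @param sites character vector of site ids.
#' @param k number of parameters (k = 0 returns an empty table, usable
#'   only by models with an identity genotype-site term).
#' @param heritable_frac fraction of within-site parameter variance
#'   attributable to the genotype component.
#' @param markers optional [marker_set()]; when supplied the genotype
#'   component is drawn from `GRM_a` (so genomic repeatability is
#'   estimable), otherwise it is i.i.d.
#' @param site_sd SD of the site component.
#' @param seed integer seed.
#' @return tibble: genotype, site, and parameter columns `par_1..par_k`.
#' @export
simulate_gs_parameters <- function(catalog, sites, k = 8,
                                   heritable_frac = 0.15, markers = NULL,
                                   site_sd = 0.7, seed = 1L) {
  if (length(sites) == 0L) abort("`sites` must be non-empty.")
  assert_count(k, "k", min = 0L)
  assert_fraction(heritable_frac, "heritable_frac", allow_zero = TRUE)
  set.seed(child_seed(seed, 4L))
  genos <- catalog$genotype_id
  n_g <- length(genos)
  grid <- tidyr::expand_grid(genotype = genos, site = as.character(sites))
  if (k == 0L) return(grid[0, ])

  L_g <- if (!is.null(markers)) {
    g <- unclass(build_grms(markers)$GRM_a)[genos, genos]
    t(chol(g + diag(1e-8, n_g)))
  } else NULL
  g_common <- if (is.null(L_g)) rnorm(n_g) else
    as.vector(L_g %*% rnorm(n_g))

  gi <- match(grid$genotype, genos)
  for (p in seq_len(k)) {
    g_spec <- if (is.null(L_g)) rnorm(n_g) else as.vector(L_g %*% rnorm(n_g))
    g_p <- sqrt(0.5) * g_common + sqrt(0.5) * g_spec
    g_p <- g_p / sd(g_p)
    s_eff <- rnorm(length(sites), sd = site_sd)
    names(s_eff) <- as.character(sites)
    noise <- rnorm(nrow(grid))
    grid[[paste0("par_", p)]] <-
      sqrt(heritable_frac) * g_p[gi] + s_eff[grid$site] +
      sqrt(1 - heritable_frac) * noise
  }
  grid
}
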