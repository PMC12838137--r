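#' Declarative kernel mixed-model specifications
#'
#' `build_model()` assembles the exact term stack of the named prediction
#' model as fixed terms plus a list of kernel-structured random terms:
#'
#' * `M_1` — identity environment + identity genotype main effects (the
#'   baseline: no genomic or environmental relationship exploited);
#' * `M_2` — identity environment + `GRM_a`/`GRM_d`/`GRM_aa` genotype terms;
#' * `M_3` / `M_5` — as `M_2` with the environment term structured by
#'   `ERM_l` / `ERM_nl`;
#' * `M_4` / `M_6` — `M_3` / `M_5` plus a multiplicative G-by-E term whose
#'   covariance is the Hadamard product of the row-expanded environment and
#'   additive genomic kernels (`GERM_1` with `ERM_l`, `GERM_2` with
#'   `ERM_nl`);
#' * `M_7` — site (`SRM`) + year (`YRM`) main effects, `GRM_a`/`GRM_d`
#'   genotype terms, a genotype-by-year term (`YRM` Hadamard `GRM_a`), an
#'   identity genotype-by-site term, and `GE_1`;
#' * `M_8` — `M_7` with the genotype-by-site term informed by a
#'   crop-growth-model parameter table (see `gs_mode`);
#' * `GBLUP_D` / `E_GBLUP_D` — across-environment models on BLUEs with
#'   `GRM_a + GRM_d` (+ `GRM_aa`);
#' * `GxE_pattern` — intercept plus identity genotype and environment
#'   random effects (used to extract G-by-E patterns from predictions);
#' * `H2` — the variance-decomposition stack built by
#'   [variance_decomposition_h2()] (Type/Series fixed; environment, line,
#'   GCA/SCA and their environment interactions random; per-environment
#'   residual variances).
#'
#' Hadamard interaction kernels are always expanded on the rows actually
#' present in `pheno` (training and prediction rows alike), never in level
#' space, so unbalanced data are handled and prediction conditions on the
#' whole kernel.
#'
#' @param name model name (see above).
#' @param pheno tibble with columns `genotype`, `environment`, `value`
#'   (`NA` value marks rows to predict), and for `M_7`/`M_8` also `site`
#'   and `year`; `H2` additionally uses `type`/`series` columns.
#' @param kernels named list of [new_kernel()] objects; which are required
#'   depends on the model (`GRM_a`, `GRM_d`, `GRM_aa`, `ERM_l`, `ERM_nl`,
#'   `YRM`, `SRM`). Missing kernels raise an error naming them.
#' @param catalog genotype catalog (needed for `H2`).
#' @param gs_params genotype-by-site parameter table for `M_8` (tibble:
#'   `genotype`, `site`, parameter columns).
#' @param gs_mode for `M_8`: `"kernel"` (default) builds a linear,
#'   mean-diagonal-normalized kernel over genotype-site cells from the
#'   standardized parameters; `"covariate"` keeps the identity
#'   genotype-site kernel and enters the parameters as fixed covariates.
#' @return a `kmm_spec` object consumed by [fit_gibbs()] and
#'   [blup_oracle()].
#' @export
build_model <- function(name, pheno, kernels = list(), catalog = NULL,
                        gs_params = NULL, gs_mode = c("kernel", "covariate")) {
  gs_mode <- match.arg(gs_mode)
  pheno <- tibble::as_tibble(pheno)
  if (!all(c("genotype", "environment", "value") %in% names(pheno))) {
    abort("`pheno` needs columns genotype, environment, value.")
  }
  pheno$genotype <- as.character(pheno$genotype)
  pheno$environment <- as.character(pheno$environment)
  need <- function(k) {
    if (is.null(kernels[[k]])) abort(sprintf("Model %s needs kernel `%s`.", name, k))
    kernels[[k]]
  }
  genos <- unique(pheno$genotype)
  envs <- unique(pheno$environment)
  terms <- list()
  fixed_formula <- ~1
  residual_group <- NULL

  rterm <- function(nm, kernel, level_cols, levels = NULL) {
    if (is.null(levels)) {
      levels <- do.call(paste, c(unname(as.list(pheno[level_cols])), sep = ":"))
    }
    miss <- setdiff(unique(levels[!is.na(levels)]), rownames(kernel))
    if (length(miss)) {
      abort(sprintf("Term %s: levels absent from kernel: %s", nm,
                    paste(head(miss, 5), collapse = ", ")))
    }
    list(name = nm, kernel = kernel, levels = levels, level_cols = level_cols)
  }
  genomic_terms <- function(with_aa = TRUE) {
    out <- list(rterm("G_a", need("GRM_a"), "genotype"),
                rterm("G_d", need("GRM_d"), "genotype"))
    if (with_aa) out <- c(out, list(rterm("G_aa", need("GRM_aa"), "genotype")))
    out
  }
  ge_term <- function(env_kernel, nm, kind) {
    cells <- dplyr::distinct(pheno, .data$environment, .data$genotype)
    kge <- hadamard_kernel(cells, env_kernel, need("GRM_a"),
                           ids = c("environment", "genotype"), kind = kind)
    rterm(nm, kge, c("environment", "genotype"))
  }

  if (name %in% c("M_7", "M_8")) {
    if (!all(c("site", "year") %in% names(pheno))) {
      abort(sprintf("Model %s needs `site` and `year` columns in pheno.", name))
    }
    pheno$site <- as.character(pheno$site)
    pheno$year <- as.character(pheno$year)
  }

  switch(
    name,
    M_1 = {
      terms <- list(rterm("E_I", identity_kernel(envs), "environment"),
                    rterm("G_I", identity_kernel(genos), "genotype"))
    },
    M_2 = {
      terms <- c(list(rterm("E_I", identity_kernel(envs), "environment")),
                 genomic_terms())
    },
    M_3 = {
      terms <- c(list(rterm("E_l", need("ERM_l"), "environment")),
                 genomic_terms())
    },
    M_4 = {
      terms <- c(list(rterm("E_l", need("ERM_l"), "environment")),
                 genomic_terms(),
                 list(ge_term(need("ERM_l"), "GE_1", "GERM_1")))
    },
    M_5 = {
      terms <- c(list(rterm("E_nl", need("ERM_nl"), "environment")),
                 genomic_terms())
    },
    M_6 = {
      terms <- c(list(rterm("E_nl", need("ERM_nl"), "environment")),
                 genomic_terms(),
                 list(ge_term(need("ERM_nl"), "GE_2", "GERM_2")))
    },
    M_7 = ,
    M_8 = {
      gy_cells <- dplyr::distinct(pheno, .data$year, .data$genotype)
      gy <- hadamard_kernel(gy_cells, need("YRM"), need("GRM_a"),
                            ids = c("year", "genotype"), kind = "GYRM_a")
      gs_levels <- paste(pheno$genotype, pheno$site, sep = ":")
      terms <- c(list(rterm("S", need("SRM"), "site"),
                      rterm("Y", need("YRM"), "year")),
                 genomic_terms(with_aa = FALSE),
                 list(rterm("GY_a", gy, c("year", "genotype"))))
      if (name == "M_7" || gs_mode == "covariate") {
        terms <- c(terms, list(rterm("GS_I", identity_kernel(unique(gs_levels)),
                                     c("genotype", "site"))))
      }
      if (name == "M_8") {
        if (is.null(gs_params)) abort("Model M_8 needs `gs_params`.")
        if (gs_mode == "kernel") {
          terms <- c(terms, list(rterm("GS", gs_param_kernel(gs_params),
                                       c("genotype", "site"))))
        }
      }
      terms <- c(terms, list(ge_term(need("ERM_l"), "GE_1", "GERM_1")))
    },
    GBLUP_D = {
      terms <- genomic_terms(with_aa = FALSE)
    },
    E_GBLUP_D = {
      terms <- genomic_terms(with_aa = TRUE)
    },
    GxE_pattern = {
      terms <- list(rterm("G_tau", identity_kernel(genos), "genotype"),
                    rterm("E_u", identity_kernel(envs), "environment"))
    },
    abort(sprintf("Unknown model `%s`.", name))
  )

  fixed_covariates <- NULL
  if (name == "M_8" && gs_mode == "covariate") {
    fixed_covariates <- gs_covariate_matrix(gs_params, pheno)
  }

  new_kmm_spec(name, pheno, fixed_formula, terms,
               residual_group = residual_group,
               fixed_covariates = fixed_covariates)
}

# linear kernel over genotype:site cells from standardized CGM parameters
gs_param_kernel <- function(gs_params) {
  gs_params <- tibble::as_tibble(gs_params)
  if (!all(c("genotype", "site") %in% names(gs_params))) {
    abort("`gs_params` needs columns genotype, site plus parameter columns.")
  }
  pcols <- setdiff(names(gs_params), c("genotype", "site"))
  if (length(pcols) == 0L) {
    abort("`gs_params` has no parameter columns (M_8 requires k >= 1).")
  }
  x <- as.matrix(gs_params[, pcols])
  rownames(x) <- paste(gs_params$genotype, gs_params$site, sep = ":")
  linear_kernel_scaled(x, kind = "GS")
}

gs_covariate_matrix <- function(gs_params, pheno) {
  gs_params <- tibble::as_tibble(gs_params)
  pcols <- setdiff(names(gs_params), c("genotype", "site"))
  if (length(pcols) == 0L) abort("`gs_params` has no parameter columns.")
  key <- paste(gs_params$genotype, gs_params$site, sep = ":")
  i <- match(paste(pheno$genotype, pheno$site, sep = ":"), key)
  if (anyNA(i)) abort("gs_params does not cover all genotype x site cells.")
  x <- scale(as.matrix(gs_params[, pcols]))
  x[, attr(x, "scaled:scale") == 0] <- 0
  m <- x[i, , drop = FALSE]
  colnames(m) <- paste0("gs_", pcols)
  m
}

new_kmm_spec <- function(name, pheno, fixed_formula, terms,
                         residual_group = NULL, fixed_covariates = NULL) {
  train <- !is.na(pheno$value)
  if (!any(train)) abort("No training rows (all `value` are NA).")
  mf <- stats::model.frame(fixed_formula, data = pheno, na.action = NULL)
  X <- stats::model.matrix(fixed_formula, mf)
  if (!is.null(fixed_covariates)) X <- cbind(X, fixed_covariates)
  structure(list(model = name, data = pheno, train = train,
                 X = X, fixed_formula = fixed_formula, terms = terms,
                 residual_group = residual_group),
            class = "kmm_spec")
}

#' @export
print.kmm_spec <- function(x, ...) {
  cat(sprintf("<kmm_spec %s: %d rows (%d training), %d random term(s): %s>\n",
              x$model, nrow(x$data), sum(x$train), length(x$terms),
              paste(vapply(x$terms, `[[`, "", "name"), collapse = ", ")))
  invisible(x)
}

# attach a per-environment residual grouping (used by the H2 model); groups
# with fewer than min_records rows share a pooled variance
with_residual_groups <- function(spec, group, min_records = 10L) {
  group <- as.character(group)
  tab <- table(group[spec$train])
  small <- names(tab)[tab < min_records]
  group[group %in% small] <- "..pooled.."
  spec$residual_group <- group
  spec
}
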