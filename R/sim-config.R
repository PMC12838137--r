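#' Simulation configuration
#'
#' Describes a synthetic multi-environment wheat trial: an elite line
#' population plus a divergent subpopulation (a gene-bank-accession
#' stand-in), hybrids from an incomplete factorial of line parents, injected
#' genomic duplicates, daily weather over sites and years, and phenotypes
#' composed of environment, additive, dominance, epistatic, G-by-E and
#' residual components with configurable variance shares.
#'
#' Default variance shares put the G-by-E interaction at one third of the
#' genetic variance (gxe / (a + d + aa) = 0.15 / 0.45), the share observed
#' for elite line material in large integrated trial networks. The grand
#' mean and total variance are on the Q/ha scale of central-European winter
#' wheat grain yield.
#'
#' One global `seed` fans out to fixed per-operation child seeds
#' (population, weather, phenotypes, crop-growth parameters), so each
#' generator is independently reproducible.
#'
#' @param n_lines,n_hybrids,n_markers,n_chromosomes,n_sites,n_years counts.
#' @param n_series number of experimental series labels to assign.
#' @param n_families number of line families (breeding crosses); lines in a
#'   family share a family-specific allele-frequency draw, giving the
#'   within-family genomic relatedness typical of elite material.
#' @param family_kinship expected within-family allele-frequency
#'   correlation (0 = unrelated lines).
#' @param factorial_density fraction of the female-by-male factorial realized.
#' @param duplicate_count exact genomic duplicates injected (extra rows).
#' @param divergent_frac fraction of lines drawn from the divergent
#'   subpopulation; `divergence` scales its allele-frequency shift (0 means
#'   no differentiation).
#' @param variance_shares named fractions summing to 1 over
#'   `env`, `a`, `d`, `aa`, `gxe`, `error` (optionally `gy`, `gs`).
#' @param sparsity fraction of genotype-by-environment cells observed.
#' @param mu,total_var grand mean and total phenotypic variance (Q/ha scale).
#' @param chrom_length chromosome length in bp for the marker map.
#' @param site_sd,year_sd,site_year_sd,day_sd weather effect scales, as
#'   multiples of each variable's natural SD.
#' @param seed global integer seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_lines = 300, n_hybrids = 200, n_markers = 1000,
                       n_chromosomes = 5, n_sites = 6, n_years = 4,
                       n_series = 5, n_families = NULL,
                       family_kinship = 0.35, factorial_density = 0.3,
                       duplicate_count = 5, divergent_frac = 0.05,
                       divergence = 0.15,
                       variance_shares = c(env = 0.25, a = 0.30, d = 0.05,
                                           aa = 0.10, gxe = 0.15, error = 0.15),
                       sparsity = 0.5, mu = 85, total_var = 64,
                       chrom_length = 6e8,
                       site_sd = 0.5, year_sd = 0.6, site_year_sd = 0.3,
                       day_sd = 1, seed = 1L) {
  for (nm in c("n_lines", "n_markers", "n_chromosomes", "n_sites", "n_years",
               "n_series")) {
    assert_count(get(nm), nm)
  }
  assert_count(n_hybrids, "n_hybrids", min = 0L)
  assert_count(duplicate_count, "duplicate_count", min = 0L)
  assert_fraction(factorial_density, "factorial_density")
  assert_fraction(sparsity, "sparsity")
  assert_fraction(divergent_frac, "divergent_frac", allow_zero = TRUE)
  required <- c("env", "a", "d", "aa", "gxe", "error")
  missing <- setdiff(required, names(variance_shares))
  if (length(missing)) {
    abort(sprintf("variance_shares missing required term(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (any(variance_shares < 0)) abort("variance_shares must be non-negative.")
  if (abs(sum(variance_shares) - 1) > 1e-9) {
    abort("variance_shares must sum to 1 within 1e-9.")
  }
  n_families <- n_families %||% max(2L, round(n_lines / 12))
  assert_fraction(family_kinship, "family_kinship", allow_zero = TRUE)
  cfg <- list(n_lines = n_lines, n_hybrids = n_hybrids, n_markers = n_markers,
              n_chromosomes = n_chromosomes, n_sites = n_sites,
              n_years = n_years, n_series = n_series,
              n_families = n_families, family_kinship = family_kinship,
              factorial_density = factorial_density,
              duplicate_count = duplicate_count,
              divergent_frac = divergent_frac, divergence = divergence,
              variance_shares = variance_shares, sparsity = sparsity,
              mu = mu, total_var = total_var, chrom_length = chrom_length,
              site_sd = site_sd, year_sd = year_sd,
              site_year_sd = site_year_sd, day_sd = day_sd,
              seed = as.integer(seed))
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config: %d lines + %d hybrids (+%d duplicates), ",
                     "%d markers, %d sites x %d years, sparsity %.2f, seed %d>\n"),
              x$n_lines, x$n_hybrids, x$duplicate_count, x$n_markers,
              x$n_sites, x$n_years, x$sparsity, x$seed))
  shares <- paste(sprintf("%s=%.2f", names(x$variance_shares),
                          x$variance_shares), collapse = ", ")
  cat("  variance shares:", shares, "\n")
  invisible(x)
}

#' Default scales of the 27 daily weather variables
#'
#' Names follow the field's sensor-style shorthand (variable_statUnit), e.g.
#' `at_maC` = daily maximum air temperature in Celsius, `ws_2_mxK` = maximum
#' wind speed at 2 m, `rh_maP` = maximum relative humidity in percent,
#' `lwr_miW` = minimum long-wave radiation. Means and SDs are plausible
#' central-European magnitudes on natural scales; the simulator only uses
#' them as location/scale anchors and makes no attempt at real meteorology.
#'
#' @return tibble with columns `variable`, `mean`, `sd`.
#' @export
ev_variable_defaults <- function() {
  tibble::tribble(
    ~variable,   ~mean, ~sd,
    "at_avC",      8.5, 2.0,
    "at_miC",      4.0, 2.2,
    "at_maC",     13.5, 2.4,
    "at_5_avC",    8.0, 2.0,
    "at_5_miC",    3.0, 2.3,
    "at_5_maC",   14.0, 2.5,
    "st_avC",      9.0, 1.8,
    "st_miC",      6.0, 1.8,
    "st_maC",     12.0, 2.0,
    "pr_suM",      1.8, 0.8,
    "pr_mxM",      8.0, 3.0,
    "rh_avP",     78.0, 6.0,
    "rh_miP",     55.0, 8.0,
    "rh_maP",     93.0, 4.0,
    "ws_2_avK",    7.0, 2.0,
    "ws_2_mxK",   16.0, 4.0,
    "ws_10_avK",  10.0, 2.5,
    "ws_10_mxK",  22.0, 5.0,
    "sr_avW",    120.0, 30.0,
    "sr_suW",    210.0, 50.0,
    "lwr_avW",   310.0, 20.0,
    "lwr_miW",   260.0, 22.0,
    "lwr_maW",   360.0, 20.0,
    "et0_suM",     1.6, 0.6,
    "vp_avH",      9.5, 2.0,
    "cc_avP",     62.0, 10.0,
    "sd_suH",      4.5, 1.5
  )
}
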