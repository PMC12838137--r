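#' Simulate daily weather for all site-year combinations
#'
#' For each of the `n_sites` x `n_years` environments, generates one daily
#' record per day of the wheat season (1 October of the sowing year to
#' 31 August of the harvest year; 29 February dropped, so always 335 days)
#' for the 27 weather variables of [ev_variable_defaults()]. Each value is
#'
#'   variable mean + site effect + year effect + site-by-year effect + noise
#'
#' with all effects on the variable's natural scale (multiples of its SD via
#' the `site_sd`, `year_sd`, `site_year_sd`, `day_sd` config entries).
#'
#' @param cfg a [sim_config()].
#' @return tibble: site, year (harvest year), environment (`site_year`),
#'   date, and one column per weather variable.
#' @export
simulate_environments <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(child_seed(cfg$seed, 2L))
  vars <- ev_variable_defaults()
  sites <- sprintf("S%02d", seq_len(cfg$n_sites))
  years <- 2018L + seq_len(cfg$n_years) - 1L

  season_dates <- function(harvest_year) {
    d <- seq(as.Date(sprintf("%d-10-01", harvest_year - 1L)),
             as.Date(sprintf("%d-08-31", harvest_year)), by = "day")
    d[format(d, "%m-%d") != "02-29"]
  }

  nv <- nrow(vars)
  site_eff <- matrix(rnorm(cfg$n_sites * nv, sd = cfg$site_sd), cfg$n_sites,
                     dimnames = list(sites, vars$variable))
  year_eff <- matrix(rnorm(cfg$n_years * nv, sd = cfg$year_sd), cfg$n_years,
                     dimnames = list(years, vars$variable))

  out <- vector("list", cfg$n_sites * cfg$n_years)
  i <- 0L
  for (s in sites) {
    for (y in years) {
      dates <- season_dates(y)
      nd <- length(dates)
      sy_eff <- rnorm(nv, sd = cfg$site_year_sd)
      vals <- vapply(seq_len(nv), function(j) {
        vars$mean[j] + vars$sd[j] *
          (site_eff[s, j] + year_eff[as.character(y), j] + sy_eff[j] +
             rnorm(nd, sd = cfg$day_sd))
      }, numeric(nd))
      colnames(vals) <- vars$variable
      i <- i + 1L
      out[[i]] <- dplyr::bind_cols(
        tibble::tibble(site = s, year = y,
                       environment = paste(s, y, sep = "_"), date = dates),
        tibble::as_tibble(vals))
    }
  }
  dplyr::bind_rows(out)
}
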