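#' Monthly environment variables from daily weather
#'
#' Aggregates daily weather to per-environment monthly means over the wheat
#' season months October (sowing year) through August (harvest year):
#' 27 variables x 11 months = 297 environment variables (EVs). Columns are
#' ordered variable-major, then month with October first
#' (`at_avC_Oct`, `at_avC_Nov`, ..., `at_avC_Aug`, `at_miC_Oct`, ...).
#'
#' @param weather tibble as returned by [simulate_environments()]: columns
#'   `site`, `year`, `environment` (optional; derived as `site_year`),
#'   `date`, plus one column per weather variable.
#' @return an `ev_matrix`: environments x EV-columns numeric matrix on the
#'   natural scale, with an `env_info` attribute (tibble: environment,
#'   site, year). Use [scale_evs()] for the per-column z-scored view.
#' @export
monthly_evs <- function(weather) {
  weather <- tibble::as_tibble(weather)
  if (!all(c("site", "year", "date") %in% names(weather))) {
    abort("`weather` needs columns site, year, date.")
  }
  if (!"environment" %in% names(weather)) {
    weather$environment <- paste(weather$site, weather$year, sep = "_")
  }
  if (anyDuplicated(weather[, c("site", "date")]) > 0L) {
    abort("Duplicate site x date rows in `weather`.")
  }
  season_months <- c(10:12, 1:8)
  month_lab <- month.abb[season_months]
  var_cols <- setdiff(names(weather), c("site", "year", "environment", "date"))
  if (length(var_cols) == 0L) abort("No weather variable columns found.")

  weather$month <- as.integer(format(as.Date(weather$date), "%m"))
  envs <- unique(weather$environment)
  env_info <- dplyr::distinct(weather, .data$environment, .data$site, .data$year)

  long <- weather |>
    dplyr::select(dplyr::all_of(c("environment", "month", var_cols))) |>
    tidyr::pivot_longer(dplyr::all_of(var_cols), names_to = "variable") |>
    dplyr::group_by(.data$environment, .data$variable, .data$month) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")

  # every environment must cover the full season
  have <- long |> dplyr::distinct(.data$environment, .data$month)
  for (e in envs) {
    missing <- setdiff(season_months, have$month[have$environment == e])
    if (length(missing)) {
      abort(sprintf("Environment %s is missing month(s): %s", e,
                    paste(month.abb[missing], collapse = ", ")))
    }
  }

  col_names <- as.vector(t(outer(var_cols, month_lab, paste, sep = "_")))
  wide <- matrix(NA_real_, length(envs), length(col_names),
                 dimnames = list(envs, col_names))
  key <- paste(long$variable, month.abb[long$month], sep = "_")
  wide[cbind(match(long$environment, envs), match(key, col_names))] <- long$value
  structure(wide, env_info = env_info[match(envs, env_info$environment), ],
            class = c("ev_matrix", class(wide)))
}

#' @rdname monthly_evs
#' @param ev an `ev_matrix`.
#' @return `scale_evs()`: the per-column z-scored matrix (columns with zero
#'   variance are set to 0).
#' @export
scale_evs <- function(ev) {
  s <- scale(unclass(ev))
  s[, attr(s, "scaled:scale") == 0] <- 0
  s <- s[, , drop = FALSE]
  attr(s, "scaled:center") <- NULL
  attr(s, "scaled:scale") <- NULL
  s
}

linear_kernel_scaled <- function(x, kind) {
  if (nrow(x) == 1L) {
    return(new_kernel(matrix(1, 1, 1, dimnames = list(rownames(x), rownames(x))),
                      kind = kind))
  }
  s <- scale(x)
  s[, attr(s, "scaled:scale") == 0 | is.na(attr(s, "scaled:scale"))] <- 0
  g <- tcrossprod(s)
  new_kernel(g / mean(diag(g)), kind = kind)
}

#' Environment, year and site relationship kernels
#'
#' From the scaled EV matrix builds:
#' * `ERM_l`  — linear kernel `EV EV' / mean(diag(EV EV'))`;
#' * `ERM_nl` — Gaussian-type kernel `exp(-dist(EV)/theta)` (Euclidean
#'   distances), normalized the same way (its diagonal is 1 by
#'   construction, so normalization is a no-op);
#' * `YRM`    — linear kernel over years, each year characterized by its
#'   mean monthly EVs across sites;
#' * `SRM`    — linear kernel over sites, each site characterized by its
#'   mean monthly EVs across years.
#'
#' @param ev an `ev_matrix` from [monthly_evs()].
#' @param theta bandwidth of the distance kernel; `"auto"` (default) uses
#'   the median off-diagonal Euclidean distance.
#' @return list with kernels `ERM_l`, `ERM_nl`, `YRM`, `SRM` and the
#'   resolved `theta`.
#' @export
build_erms <- function(ev, theta = "auto") {
  if (nrow(ev) < 2L) abort("Need at least 2 environments.")
  evs <- scale_evs(ev)
  g <- tcrossprod(evs)
  erm_l <- new_kernel(g / mean(diag(g)), kind = "ERM_l")

  d <- as.matrix(dist(evs))
  if (identical(theta, "auto")) theta <- median(d[upper.tri(d)])
  if (!is.numeric(theta) || theta <= 0) abort("`theta` must be positive.")
  knl <- exp(-d / theta)
  erm_nl <- new_kernel(knl / mean(diag(knl)), kind = "ERM_nl")

  info <- attr(ev, "env_info")
  if (is.null(info)) {
    abort("`ev` lacks env_info (site/year); build it with monthly_evs().")
  }
  year_means <- rowsum(unclass(ev), as.character(info$year), reorder = TRUE)
  year_means <- year_means / as.vector(table(as.character(info$year)))
  site_means <- rowsum(unclass(ev), as.character(info$site), reorder = TRUE)
  site_means <- site_means / as.vector(table(as.character(info$site)))

  list(ERM_l = erm_l, ERM_nl = erm_nl,
       YRM = linear_kernel_scaled(year_means, "YRM"),
       SRM = linear_kernel_scaled(site_means, "SRM"),
       theta = theta)
}

#' Hierarchical clustering of environments
#'
#' Average-linkage agglomerative clustering on Euclidean distances of the
#' scaled EV matrix (or on `1 - kernel` values, or a distance matrix
#' directly). The cophenetic matrix is retained for tree comparison.
#'
#' @param x an `ev_matrix`, a `kernel`, or a symmetric distance matrix.
#' @return an `env_dendrogram`: list with `hclust`, `cophenetic` (matrix),
#'   and the `dist` used.
#' @export
cluster_environments <- function(x) {
  if (inherits(x, "ev_matrix")) {
    d <- dist(scale_evs(x))
  } else if (inherits(x, "kernel")) {
    d <- stats::as.dist(pmax(1 - unclass(x), 0))
  } else if (is.matrix(x) && isSymmetric(unname(x))) {
    d <- stats::as.dist(x)
  } else {
    abort("`x` must be an ev_matrix, kernel, or symmetric distance matrix.")
  }
  if (attr(d, "Size") < 3L) abort("Need at least 3 environments to cluster.")
  hc <- hclust(d, method = "average")
  structure(list(hclust = hc, cophenetic = as.matrix(cophenetic(hc)), dist = d),
            class = "env_dendrogram")
}

#' @export
print.env_dendrogram <- function(x, ...) {
  cat(sprintf("<env_dendrogram: %d leaves, average linkage>\n",
              length(x$hclust$labels)))
  invisible(x)
}

#' Export a dendrogram as Newick
#'
#' @param x an `env_dendrogram` or `hclust`.
#' @param path output file.
#' @export
write_dendrogram_newick <- function(x, path) {
  hc <- if (inherits(x, "env_dendrogram")) x$hclust else x
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
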