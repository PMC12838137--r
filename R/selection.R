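#' Curate a reference set from across-environment BLUEs
#'
#' Subset 1 is the top `top_frac` of genotypes by BLUE; subset 2 is a
#' seeded uniform sample of `random_frac` from the remainder (set sizes by
#' ceiling). The two subsets are disjoint by construction.
#'
#' @param blues tibble with `genotype_id` and `blue` (one row per
#'   genotype, e.g. from [estimate_blues()] collapsed to canonical ids).
#' @param top_frac,random_frac subset fractions (must sum to at most 1).
#' @param seed integer seed for the random subset.
#' @return tibble: genotype_id, blue, subset (`"top"`/`"random"`).
#' @export
curate_reference_set <- function(blues, top_frac = 0.07, random_frac = 0.03,
                                 seed = 1L) {
  if (top_frac + random_frac > 1) abort("Subset fractions must sum to <= 1.")
  blues <- tibble::as_tibble(blues)
  n <- nrow(blues)
  n_top <- ceiling(top_frac * n)
  n_rand <- ceiling(random_frac * n)
  if (n_top + n_rand > n) abort("Population too small for both subsets.")
  top_ids <- top_k_ids(blues$genotype_id, blues$blue, n_top)
  rest <- dplyr::filter(blues, !(.data$genotype_id %in% top_ids))
  set.seed(as.integer(seed))
  rand_ids <- if (n_rand > 0 && nrow(rest) > 0) {
    sample(rest$genotype_id, min(n_rand, nrow(rest)))
  } else character()
  dplyr::bind_rows(
    dplyr::mutate(dplyr::filter(blues, .data$genotype_id %in% top_ids),
                  subset = "top"),
    dplyr::mutate(dplyr::filter(blues, .data$genotype_id %in% rand_ids),
                  subset = "random"))
}

#' Enviromically adapted genotypes per environment
#'
#' The top `top_frac` (by ceiling) of genotypes by predicted yield within
#' each environment; ties broken by genotype id so the sets are
#' deterministic.
#'
#' @param predictions genotype-by-environment prediction matrix over the
#'   reference set.
#' @param top_frac fraction selected per environment.
#' @return named list: environment -> character vector of genotype ids.
#' @export
enviromically_adapted <- function(predictions, top_frac = 0.10) {
  assert_fraction(top_frac, "top_frac")
  k <- ceiling(top_frac * nrow(predictions))
  ids <- rownames(predictions)
  out <- lapply(colnames(predictions), function(e)
    top_k_ids(ids, predictions[, e], k))
  setNames(out, colnames(predictions))
}

#' Selection gain of enviromically adapted versus overall-top genotypes
#'
#' Per environment, compares the mean predicted yield of (a) the
#' environment-specific adapted set and (b) the `overall_top_n` genotypes
#' ranked by across-environment BLUE, both expressed as gains over the
#' reference-set mean in that environment. Their difference (the boost) is
#' converted to breeding-progress years by dividing by the annual genetic
#' yield gain `rate`.
#'
#' @param predictions genotype-by-environment prediction matrix over the
#'   reference set.
#' @param blues tibble `genotype_id`, `blue` covering the reference set
#'   (used to rank overall performers).
#' @param adapted optional list from [enviromically_adapted()]; computed
#'   at `top_frac` when missing.
#' @param overall_top_n size of the overall-performer set.
#' @param top_frac passed to [enviromically_adapted()] when needed.
#' @param rate annual genetic yield gain (Q/ha/year) for the years
#'   conversion.
#' @return a `selection_report`: list with `per_environment` (tibble:
#'   environment, reference_mean, gain_adapted, gain_overall, boost,
#'   breeding_progress_years) and `summary` (means over environments).
#' @export
selection_gain <- function(predictions, blues, adapted = NULL,
                           overall_top_n = 50, top_frac = 0.10,
                           rate = 0.32) {
  ids <- rownames(predictions)
  blues <- dplyr::filter(tibble::as_tibble(blues), .data$genotype_id %in% ids)
  if (overall_top_n > nrow(blues)) {
    abort("`overall_top_n` exceeds the reference set size.")
  }
  if (is.null(adapted)) {
    adapted <- enviromically_adapted(predictions, top_frac = top_frac)
  }
  overall_ids <- top_k_ids(blues$genotype_id, blues$blue, overall_top_n)
  rows <- lapply(colnames(predictions), function(e) {
    ref_mean <- mean(predictions[, e])
    gain_ad <- mean(predictions[adapted[[e]], e]) - ref_mean
    gain_ov <- mean(predictions[overall_ids, e]) - ref_mean
    tibble::tibble(environment = e, reference_mean = ref_mean,
                   gain_adapted = gain_ad, gain_overall = gain_ov,
                   boost = gain_ad - gain_ov,
                   breeding_progress_years = (gain_ad - gain_ov) / rate)
  })
  per_env <- dplyr::bind_rows(rows)
  structure(list(
    per_environment = per_env,
    overall_ids = overall_ids, adapted = adapted, rate = rate,
    summary = tibble::tibble(
      mean_gain_adapted = mean(per_env$gain_adapted),
      mean_gain_overall = mean(per_env$gain_overall),
      mean_boost = mean(per_env$boost),
      max_boost = max(per_env$boost),
      mean_breeding_progress_years = mean(per_env$breeding_progress_years))),
    class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<selection_report: %d environments; mean gain ",
                     "adapted %.2f vs overall %.2f Q/ha; mean boost %.2f ",
                     "(%.1f breeding-progress years)>\n"),
              nrow(x$per_environment), s$mean_gain_adapted,
              s$mean_gain_overall, s$mean_boost,
              s$mean_breeding_progress_years))
  invisible(x)
}

#' Overlap of adapted sets within versus between environment clusters
#'
#' Mean pairwise intersection size of the per-environment adapted sets for
#' environment pairs in the same cluster versus pairs in different
#' clusters.
#'
#' @param adapted list from [enviromically_adapted()].
#' @param clusters a `cluster_assignment` (or tibble environment/cluster)
#'   sharing the environment ids.
#' @return list with `overall` (tibble: within, between) and
#'   `per_cluster`; singleton clusters report `NA` within-cluster overlap.
#' @export
cluster_overlap <- function(adapted, clusters) {
  assign <- if (inherits(clusters, "cluster_assignment"))
    clusters$assignment else tibble::as_tibble(clusters)
  envs <- intersect(names(adapted), assign$environment)
  if (!length(envs)) abort("Adapted sets and clusters share no environments.")
  cl <- setNames(assign$cluster, assign$environment)[envs]
  pairs <- utils::combn(envs, 2, simplify = FALSE)
  ov <- vapply(pairs, function(p)
    length(intersect(adapted[[p[1]]], adapted[[p[2]]])), numeric(1))
  same <- vapply(pairs, function(p) cl[p[1]] == cl[p[2]], logical(1))
  per_cluster <- lapply(unique(cl), function(cc) {
    in_cc <- vapply(pairs, function(p)
      cl[p[1]] == cc & cl[p[2]] == cc, logical(1))
    tibble::tibble(cluster = cc, n_environments = sum(cl == cc),
                   within = if (any(in_cc)) mean(ov[in_cc]) else NA_real_)
  })
  list(overall = tibble::tibble(
    within = if (any(same)) mean(ov[same]) else NA_real_,
    between = if (any(!same)) mean(ov[!same]) else NA_real_),
    per_cluster = dplyr::bind_rows(per_cluster))
}
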