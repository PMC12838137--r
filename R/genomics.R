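#' Marker quality control
#'
#' Drops markers whose missing fraction exceeds `max_missing`, monomorphic
#' markers, and markers below the minor-allele-frequency threshold, then
#' imputes any remaining missing calls with the per-marker mean code
#' rounded to the nearest integer (the in-package fallback for
#' haplotype-based imputation; synthetic data are complete anyway).
#'
#' @param m a [marker_set()].
#' @param max_missing maximum tolerated missing fraction per marker.
#' @param maf_min minimum minor allele frequency (computed after dropping
#'   missing calls).
#' @return a filtered, fully imputed `marker_set`; marker order preserved.
#' @export
filter_markers <- function(m, max_missing = 0.5, maf_min = 0.01) {
  assert_fraction(max_missing, "max_missing", allow_zero = TRUE)
  assert_fraction(maf_min, "maf_min", allow_zero = TRUE)
  codes <- m$codes
  miss_frac <- colMeans(is.na(codes))
  p <- colMeans(codes, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- miss_frac <= max_missing & maf >= maf_min & maf > 0
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) abort("No markers survive filtering.")
  out <- subset_markers(m, which(keep))
  if (anyNA(out$codes)) {
    means <- round(colMeans(out$codes, na.rm = TRUE))
    idx <- which(is.na(out$codes), arr.ind = TRUE)
    out$codes[idx] <- means[idx[, 2]]
  }
  out
}

#' Rogers' genetic distance
#'
#' For biallelic markers coded 0/1/2 the Rogers distance between genotypes
#' x and y is the mean over markers of |c_x - c_y| / 2 (codes halved to
#' within-individual allele frequencies): 0 for identical genotypes, 1 for
#' opposite homozygotes at every locus.
#'
#' @param m a complete (no missing calls) [marker_set()].
#' @return symmetric genotypes x genotypes distance matrix, zero diagonal.
#' @export
rogers_distance <- function(m) {
  if (anyNA(m$codes)) {
    abort("Missing marker codes; run filter_markers() first.")
  }
  d <- as.matrix(dist(m$codes, method = "manhattan")) / (2 * ncol(m$codes))
  d
}

#' Genomic deduplication
#'
#' Groups genotypes whose pairwise distance is below `threshold`
#' (single-linkage: the transitive closure of all below-threshold pairs,
#' which for inbred material corresponds to the F6-or-later identity rule)
#' and maps every member to the lexicographically smallest id of its group.
#'
#' @param d symmetric distance matrix (e.g. from [rogers_distance()]).
#' @param threshold distance below which a pair counts as duplicates.
#' @return tibble `genotype_id`, `canonical_id`; the map is idempotent.
#' @export
deduplicate <- function(d, threshold = 0.03) {
  ids <- rownames(d)
  adj <- d < threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  canonical <- vapply(split(ids, comp), function(v) min(v), character(1))
  tibble::tibble(genotype_id = ids,
                 canonical_id = unname(canonical[as.character(comp)]))
}

apply_dedup <- function(ids, dedup) {
  if (is.null(dedup)) return(as.character(ids))
  i <- match(as.character(ids), dedup$genotype_id)
  out <- dedup$canonical_id[i]
  out[is.na(i)] <- as.character(ids)[is.na(i)]
  out
}

#' Genomic relationship matrices
#'
#' Builds the three genomic kernels used by the prediction models:
#' * `GRM_a`  — additive, VanRaden method 1: `W W' / (2 sum p_j (1-p_j))`
#'   with `W = codes - 2p`;
#' * `GRM_d`  — dominance with orthogonal coding
#'   `{0 -> -2p^2, 1 -> 2p(1-p), 2 -> -2(1-p)^2}`, scaled by
#'   `sum (2 p_j (1-p_j))^2`;
#' * `GRM_aa` — additive-by-additive epistasis as the Hadamard square of
#'   `GRM_a`, normalized so its mean diagonal is 1.
#'
#' @param m a filtered, imputed [marker_set()] with at least 2 genotypes.
#' @return list of kernels `GRM_a`, `GRM_d`, `GRM_aa`.
#' @export
build_grms <- function(m) {
  codes <- m$codes
  if (anyNA(codes)) abort("Missing codes; run filter_markers() first.")
  if (nrow(codes) < 2L) abort("Need at least 2 genotypes.")
  p <- colMeans(codes) / 2
  if (any(p %in% c(0, 1))) {
    abort("Monomorphic markers present; run filter_markers() first.")
  }
  w <- sweep(codes, 2, 2 * p)
  grm_a <- tcrossprod(w) / (2 * sum(p * (1 - p)))

  dcode <- matrix(0, nrow(codes), ncol(codes), dimnames = dimnames(codes))
  p2 <- matrix(p, nrow(codes), ncol(codes), byrow = TRUE)
  dcode[codes == 0] <- (-2 * p2^2)[codes == 0]
  dcode[codes == 1] <- (2 * p2 * (1 - p2))[codes == 1]
  dcode[codes == 2] <- (-2 * (1 - p2)^2)[codes == 2]
  grm_d <- tcrossprod(dcode) / sum((2 * p * (1 - p))^2)

  aa <- grm_a * grm_a
  grm_aa <- aa / mean(diag(aa))

  list(GRM_a = new_kernel(grm_a, "GRM_a"),
       GRM_d = new_kernel(grm_d, "GRM_d"),
       GRM_aa = new_kernel(grm_aa, "GRM_aa"))
}

#' Derive hybrid marker profiles from parental lines
#'
#' Hybrid code = (female code + male code) / 2, so crosses of opposite
#' homozygotes yield heterozygous calls (code 1).
#'
#' @param lines a [marker_set()] holding all parents.
#' @param catalog genotype catalog tibble; only `material_type == "hybrid"`
#'   rows are used.
#' @return a `marker_set` containing the hybrids only, in catalog order.
#' @export
derive_hybrid_genotypes <- function(lines, catalog) {
  hy <- dplyr::filter(catalog, .data$material_type == "hybrid")
  if (nrow(hy) == 0L) abort("Catalog contains no hybrids.")
  missing <- !(hy$female_parent %in% rownames(lines$codes)) |
    !(hy$male_parent %in% rownames(lines$codes))
  if (any(missing)) {
    abort(sprintf("Missing parent genotypes for hybrid(s): %s",
                  paste(head(hy$genotype_id[missing], 5), collapse = ", ")))
  }
  codes <- (lines$codes[hy$female_parent, , drop = FALSE] +
              lines$codes[hy$male_parent, , drop = FALSE]) / 2
  rownames(codes) <- hy$genotype_id
  marker_set(codes, lines$map)
}

#' Principal coordinate analysis
#'
#' Classical metric multidimensional scaling of a distance matrix:
#' eigendecomposition of the double-centered `-D^2/2`, coordinates scaled
#' by the square root of the eigenvalues. Axis signs follow a deterministic
#' convention (the largest-magnitude loading on each axis is positive).
#'
#' @param d symmetric distance matrix.
#' @param k number of coordinates requested; truncated with a warning when
#'   it exceeds the number of positive eigenvalues.
#' @return list with `coordinates` (n x k' matrix) and `eigenvalues`.
#' @export
pcoa <- function(d, k = 2) {
  assert_count(k, "k")
  fit <- suppressWarnings(
    cmdscale(stats::as.dist(d), k = min(k, nrow(as.matrix(d)) - 1L),
             eig = TRUE))
  pos <- sum(fit$eig > 1e-10)
  if (k > pos) {
    warn(sprintf("Only %d positive eigenvalues; returning %d coordinate(s).",
                 pos, pos))
    k <- pos
  }
  coords <- fit$points[, seq_len(k), drop = FALSE]
  for (j in seq_len(ncol(coords))) {
    i_max <- which.max(abs(coords[, j]))
    if (coords[i_max, j] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords, eigenvalues = fit$eig)
}
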