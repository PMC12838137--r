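#' Windowed Weir-Cockerham Fst between groups of genotypes
#'
#' Computes the Weir & Cockerham (1984) fixation index for every pair of
#' groups, window-wise along the genome: windows of `window_bp` base pairs
#' advanced by `step_bp` per chromosome (half-open `[start, start +
#' window)`, 1-based positions, so consecutive starts are 1, 1 + step,
#' ...). The weighted estimate is the ratio of sums — per-window
#' among-population variance components summed over windows, divided by
#' the summed total components — which equals the single-window estimate
#' when one window covers all markers.
#'
#' @param m a complete [marker_set()].
#' @param groups named character vector mapping genotype id to group
#'   (e.g. experimental series), or a tibble with columns `genotype_id`
#'   and `group`/`series`.
#' @param window_bp,step_bp window and step size in base pairs.
#' @return an `fst_result`: list with `fst` (symmetric group matrix of
#'   weighted estimates), `windows` (per pair/chromosome/window tibble)
#'   and `hclust` (average-linkage tree on the Fst matrix).
#' @export
windowed_fst <- function(m, groups, window_bp = 299999, step_bp = 29999) {
  if (anyNA(m$codes)) abort("Missing codes; run filter_markers() first.")
  if (is.data.frame(groups)) {
    gcol <- intersect(c("group", "series"), names(groups))[1]
    groups <- setNames(as.character(groups[[gcol]]), groups$genotype_id)
  }
  groups <- groups[intersect(names(groups), rownames(m$codes))]
  glev <- sort(unique(groups))
  if (length(glev) < 2L) abort("Need at least 2 groups.")
  sizes <- table(groups)
  if (any(sizes < 2)) {
    abort(sprintf("Group(s) with < 2 genotypes: %s",
                  paste(names(sizes)[sizes < 2], collapse = ", ")))
  }

  pairs <- utils::combn(glev, 2, simplify = FALSE)
  fst_mat <- matrix(0, length(glev), length(glev),
                    dimnames = list(glev, glev))
  win_rows <- list()

  for (pr in pairs) {
    ids1 <- names(groups)[groups == pr[1]]
    ids2 <- names(groups)[groups == pr[2]]
    comp <- wc_components(m$codes[ids1, , drop = FALSE],
                          m$codes[ids2, , drop = FALSE])
    num_tot <- 0
    den_tot <- 0
    for (ch in unique(m$map$chrom)) {
      on_ch <- m$map$chrom == ch
      pos <- m$map$pos[on_ch]
      a_ch <- comp$a[on_ch]
      abc_ch <- comp$abc[on_ch]
      L <- max(pos)
      starts <- if (L <= window_bp) 1 else
        1 + step_bp * (0:ceiling((L - window_bp) / step_bp))
      for (s in starts) {
        in_w <- pos >= s & pos < s + window_bp
        if (!any(in_w)) next
        num <- sum(a_ch[in_w])
        den <- sum(abc_ch[in_w])
        num_tot <- num_tot + num
        den_tot <- den_tot + den
        win_rows[[length(win_rows) + 1L]] <- tibble::tibble(
          group1 = pr[1], group2 = pr[2], chrom = ch, start = s,
          n_markers = sum(in_w),
          fst = if (den > 0) num / den else NA_real_)
      }
    }
    fst_mat[pr[1], pr[2]] <- fst_mat[pr[2], pr[1]] <-
      if (den_tot > 0) num_tot / den_tot else NA_real_
  }

  hc <- if (length(glev) >= 3L) {
    hclust(stats::as.dist(fst_mat), method = "average")
  } else NULL
  structure(list(fst = fst_mat, windows = dplyr::bind_rows(win_rows),
                 hclust = hc),
            class = "fst_result")
}

# Weir & Cockerham (1984) per-marker variance components for two
# populations: a (among populations), b (among individuals within), c
# (within individuals). Heterozygote frequencies come from code == 1.
wc_components <- function(codes1, codes2) {
  n1 <- nrow(codes1); n2 <- nrow(codes2)
  p1 <- colMeans(codes1) / 2
  p2 <- colMeans(codes2) / 2
  h1 <- colMeans(codes1 == 1)
  h2 <- colMeans(codes2 == 1)
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  c_ <- hbar / 2
  list(a = a, abc = a + b + c_)
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("<fst_result: %d groups, %d windows>\n", nrow(x$fst),
              nrow(x$windows)))
  print(round(x$fst, 4))
  invisible(x)
}
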