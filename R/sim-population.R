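#' Simulate a line/hybrid breeding population
#'
#' Generates fully homozygous line genotypes (codes 0/2) from per-marker
#' allele frequencies, a divergent subpopulation drawn from shifted
#' frequencies (a gene-bank stand-in concentrated in the last experimental
#' series), hybrids as means of parental codes from an incomplete factorial
#' of female-by-male crosses, and exact genomic duplicates under new
#' identifiers. Monomorphic markers are repaired by flipping one random
#' line, so per-marker MAF is at least 1/(2n).
#'
#' @param cfg a [sim_config()].
#' @return list with `markers` (a [marker_set()] over lines, duplicates and
#'   hybrids) and `catalog` (tibble: genotype_id, material_type,
#'   female_parent, male_parent, series).
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(child_seed(cfg$seed, 1L))

  n_div <- round(cfg$divergent_frac * cfg$n_lines)
  n_elite <- cfg$n_lines - n_div
  p <- runif(cfg$n_markers, 0.1, 0.9)
  p_div <- pmin(pmax(p + cfg$divergence * rnorm(cfg$n_markers), 0.02), 0.98)

  # family-structured line sampling: lines within a family (breeding cross)
  # share a Beta-drawn family allele frequency, so within-family genomic
  # relatedness matches elite material; family_kinship = 0 gives unrelated
  # lines
  draw_lines <- function(n, freq) {
    if (n == 0) return(NULL)
    if (cfg$family_kinship == 0 || cfg$n_families >= n) {
      return(matrix(rbinom(n * length(freq), 1L,
                           rep(freq, each = n)) * 2, nrow = n))
    }
    nu <- 1 / cfg$family_kinship - 1
    fam <- sort(rep_len(seq_len(min(cfg$n_families, n)), n))
    m <- matrix(0L, n, length(freq))
    for (f in unique(fam)) {
      pf <- rbeta(length(freq), nu * freq, nu * (1 - freq))
      rows <- which(fam == f)
      m[rows, ] <- matrix(rbinom(length(rows) * length(freq), 1L,
                                 rep(pf, each = length(rows))) * 2,
                          nrow = length(rows))
    }
    m
  }
  line_codes <- rbind(draw_lines(n_elite, p),
                      if (n_div > 0) draw_lines(n_div, p_div))
  line_ids <- sprintf("L%04d", seq_len(cfg$n_lines))
  rownames(line_codes) <- line_ids

  # repair monomorphic markers: flip one random line
  freq_hat <- colMeans(line_codes) / 2
  for (j in which(freq_hat %in% c(0, 1))) {
    i <- sample.int(cfg$n_lines, 1L)
    line_codes[i, j] <- 2 - line_codes[i, j]
  }

  series_labels <- sprintf("Exp_%d", seq_len(cfg$n_series))
  elite_series <- sample(series_labels[-cfg$n_series], n_elite, replace = TRUE)
  line_series <- c(elite_series, rep(series_labels[cfg$n_series], n_div))
  if (n_div == 0) line_series <- sample(series_labels, cfg$n_lines, replace = TRUE)

  # incomplete factorial: females from the first half, males from the second
  catalog <- tibble::tibble(genotype_id = line_ids, material_type = "line",
                            female_parent = NA_character_,
                            male_parent = NA_character_, series = line_series)
  hybrid_codes <- NULL
  if (cfg$n_hybrids > 0) {
    n_f <- max(2L, floor(cfg$n_lines / 2))
    females <- line_ids[seq_len(n_f)]
    males <- line_ids[(n_f + 1):cfg$n_lines]
    possible <- length(females) * length(males)
    available <- floor(cfg$factorial_density * possible)
    if (available < cfg$n_hybrids) {
      abort(sprintf(paste0("factorial_density %.2f of a %d x %d factorial ",
                           "yields only %d crosses; %d hybrids requested."),
                    cfg$factorial_density, length(females), length(males),
                    available, cfg$n_hybrids))
    }
    cross_idx <- sample.int(possible, cfg$n_hybrids)
    f_idx <- ((cross_idx - 1L) %% length(females)) + 1L
    m_idx <- ((cross_idx - 1L) %/% length(females)) + 1L
    hybrid_ids <- sprintf("H%04d", seq_len(cfg$n_hybrids))
    hybrid_codes <- (line_codes[females[f_idx], , drop = FALSE] +
                       line_codes[males[m_idx], , drop = FALSE]) / 2
    rownames(hybrid_codes) <- hybrid_ids
    catalog <- dplyr::bind_rows(catalog, tibble::tibble(
      genotype_id = hybrid_ids, material_type = "hybrid",
      female_parent = females[f_idx], male_parent = males[m_idx],
      series = line_series[match(females[f_idx], line_ids)]))
  }

  dup_codes <- NULL
  if (cfg$duplicate_count > 0) {
    dup_src <- sample(line_ids, cfg$duplicate_count)
    dup_ids <- paste0(dup_src, "_dup")
    dup_codes <- line_codes[dup_src, , drop = FALSE]
    rownames(dup_codes) <- dup_ids
    catalog <- dplyr::bind_rows(catalog, tibble::tibble(
      genotype_id = dup_ids, material_type = "line",
      female_parent = NA_character_, male_parent = NA_character_,
      series = line_series[match(dup_src, line_ids)]))
  }

  codes <- rbind(line_codes, dup_codes, hybrid_codes)
  marker_ids <- sprintf("M%05d", seq_len(cfg$n_markers))
  colnames(codes) <- marker_ids
  per_chrom <- rep(cfg$n_markers %/% cfg$n_chromosomes, cfg$n_chromosomes)
  extra <- cfg$n_markers %% cfg$n_chromosomes
  if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
  map <- tibble::tibble(
    marker_id = marker_ids,
    chrom = rep(sprintf("chr%d", seq_len(cfg$n_chromosomes)), per_chrom),
    pos = unlist(lapply(per_chrom, function(k)
      sort(sample.int(cfg$chrom_length, k))))
  )
  list(markers = marker_set(codes, map), catalog = catalog)
}
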