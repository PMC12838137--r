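#' Marker matrix container
#'
#' Biallelic SNP codes (0/1/2, `NA` for missing) for a set of genotypes,
#' together with a marker map (chromosome, 1-based bp position). Codes are
#' stored as a genotypes-by-markers integer matrix with dimnames; the map is
#' a tibble aligned to the marker columns.
#'
#' @param codes genotypes x markers matrix with values in \{0, 1, 2, NA\}.
#' @param map tibble with columns `marker_id`, `chrom`, `pos` aligned to
#'   `colnames(codes)`.
#' @return object of class `marker_set`.
#' @export
marker_set <- function(codes, map) {
  if (!is.matrix(codes)) abort("`codes` must be a matrix.")
  if (is.null(rownames(codes)) || is.null(colnames(codes))) {
    abort("`codes` needs genotype row names and marker column names.")
  }
  if (anyDuplicated(colnames(codes)) > 0L) abort("Marker ids must be unique.")
  if (anyDuplicated(rownames(codes)) > 0L) abort("Genotype ids must be unique.")
  bad <- !is.na(codes) & !(codes %in% c(0, 1, 2))
  if (any(bad)) abort("Marker codes must be 0, 1, 2 or NA.")
  map <- tibble::as_tibble(map)
  if (!all(c("marker_id", "chrom", "pos") %in% names(map))) {
    abort("`map` needs columns marker_id, chrom, pos.")
  }
  if (!identical(as.character(map$marker_id), colnames(codes))) {
    abort("`map$marker_id` must align with the marker columns.")
  }
  structure(list(codes = codes, map = map), class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set: %d genotypes x %d markers on %d chromosome(s); %d missing calls>\n",
              nrow(x$codes), ncol(x$codes), length(unique(x$map$chrom)),
              sum(is.na(x$codes))))
  invisible(x)
}

#' @export
dim.marker_set <- function(x) dim(x$codes)

genotype_ids <- function(m) rownames(m$codes)

subset_markers <- function(m, marker_keep) {
  marker_set(m$codes[, marker_keep, drop = FALSE],
             m$map[match(colnames(m$codes)[marker_keep], m$map$marker_id), ])
}

subset_genotypes <- function(m, ids) {
  marker_set(m$codes[ids, , drop = FALSE], m$map)
}

#' Write / read marker data as CSV
#'
#' The marker CSV has genotypes as rows (first column `genotype_id`) and
#' markers as columns with 0/1/2 codes; the side-car map CSV has columns
#' `marker_id`, `chrom`, `pos` (1-based bp).
#'
#' @param m a `marker_set`.
#' @param path path of the marker CSV; the map is written next to it with
#'   suffix `_map.csv` unless `map_path` is given.
#' @param map_path optional explicit map path.
#' @export
write_marker_csv <- function(m, path, map_path = NULL) {
  map_path <- map_path %||% sub("\\.csv$", "_map.csv", path)
  df <- data.frame(genotype_id = rownames(m$codes), m$codes, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  utils::write.csv(m$map, map_path, row.names = FALSE)
  invisible(c(path, map_path))
}

#' @rdname write_marker_csv
#' @export
read_marker_csv <- function(path, map_path = NULL) {
  map_path <- map_path %||% sub("\\.csv$", "_map.csv", path)
  df <- utils::read.csv(path, check.names = FALSE)
  codes <- as.matrix(df[, -1, drop = FALSE])
  rownames(codes) <- as.character(df[[1]])
  storage.mode(codes) <- "double"
  marker_set(codes, utils::read.csv(map_path))
}

#' Write a minimal VCF (GT-only, unphased) for a marker set
#'
#' Codes 0/1/2 become genotypes 0/0, 0/1, 1/1 with placeholder REF/ALT
#' alleles; missing codes become `./.`.
#'
#' @param m a `marker_set`.
#' @param path output `.vcf` path (uncompressed).
#' @export
write_marker_vcf <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(m$codes)), collapse = "\t")),
             con)
  gt_map <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (j in seq_len(ncol(m$codes))) {
    cj <- m$codes[, j]
    gt <- ifelse(is.na(cj), "./.", gt_map[as.character(cj)])
    writeLines(paste(c(as.character(m$map$chrom[j]), m$map$pos[j],
                       m$map$marker_id[j], "A", "G", ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a minimal biallelic VCF into a marker set
#'
#' Uses vcfR; only biallelic records with a GT field are accepted.
#'
#' @param path a `.vcf` file.
#' @return a `marker_set` with codes counting ALT alleles.
#' @export
read_marker_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("Reading VCF requires the vcfR package.")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) abort("Only biallelic VCF records are supported.")
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(g) {
    ifelse(is.na(g) | g %in% c("./.", ".|."), NA_real_,
           vapply(strsplit(gsub("\\|", "/", g), "/"),
                  function(a) sum(a == "1"), numeric(1)))
  }
  codes <- t(apply(gt, 2, count_alt))
  # t(apply) on a single-sample matrix needs explicit shaping
  codes <- matrix(codes, nrow = ncol(gt), ncol = nrow(gt),
                  dimnames = list(colnames(gt), fix[, "ID"]))
  marker_set(codes, tibble::tibble(marker_id = fix[, "ID"],
                                   chrom = fix[, "CHROM"],
                                   pos = as.integer(fix[, "POS"])))
}
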