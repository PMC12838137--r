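test_that("filter_markers drops monomorphic, high-missing and rare markers", {
  m <- toy_markers()
  # m4 is monomorphic (all 0), others polymorphic
  out <- filter_markers(m, max_missing = 0.5, maf_min = 0.01)
  expect_equal(colnames(out$codes), c("m1", "m2", "m3", "m5"))
  # missing fraction above threshold drops the marker
  codes <- m$codes
  codes[1:3, "m1"] <- NA  # 3/4 = 0.75 missing
  m2 <- marker_set(codes, m$map)
  out2 <- filter_markers(m2, max_missing = 0.5)
  expect_false("m1" %in% colnames(out2$codes))
  # a MAF = 0.005 marker is removed at maf_min = 0.01
  big <- matrix(2, 100, 5,
                dimnames = list(sprintf("g%03d", 1:100), paste0("m", 1:5)))
  big[, 1:4] <- rbinom(400, 2, 0.5)
  big[1, 5] <- 1  # allele frequency 1/200
  m3 <- marker_set(big, tibble::tibble(marker_id = paste0("m", 1:5),
                                       chrom = "chr1", pos = 1:5 * 100L))
  out3 <- filter_markers(m3, maf_min = 0.01)
  expect_equal(ncol(out3$codes), 4)
  # imputation fills remaining NAs with rounded means
  codes4 <- m$codes
  codes4[1, "m2"] <- NA
  out4 <- filter_markers(marker_set(codes4, m$map))
  expect_false(anyNA(out4$codes))
  expect_equal(out4$codes[1, "m2"], round(mean(c(2, 0, 2))))
  expect_error(filter_markers(m, maf_min = 1), "No markers survive")
})

test_that("rogers_distance matches hand computation and brute force", {
  codes <- rbind(x = c(0, 2, 2), y = c(2, 2, 0), z = c(0, 2, 2))
  colnames(codes) <- paste0("m", 1:3)
  m <- marker_set(codes, tibble::tibble(marker_id = paste0("m", 1:3),
                                        chrom = "chr1", pos = 1:3 * 10L))
  d <- rogers_distance(m)
  expect_equal(d["x", "y"], 2 / 3)
  expect_equal(d["x", "z"], 0)
  # opposite homozygotes at every locus -> 1
  opp <- marker_set(rbind(a = c(0, 0, 0), b = c(2, 2, 2)) |>
                      `colnames<-`(paste0("m", 1:3)),
                    tibble::tibble(marker_id = paste0("m", 1:3),
                                   chrom = "chr1", pos = 1:3 * 10L))
  expect_equal(rogers_distance(opp)["a", "b"], 1)
  # brute force via within-individual allele frequencies
  set.seed(1)
  rc <- matrix(sample(0:2, 40, replace = TRUE), 4,
               dimnames = list(paste0("g", 1:4), paste0("m", 1:10)))
  mm <- marker_set(rc, tibble::tibble(marker_id = paste0("m", 1:10),
                                      chrom = "chr1", pos = 1:10 * 10L))
  dd <- rogers_distance(mm)
  brute <- mean(abs(rc[1, ] / 2 - rc[2, ] / 2))
  expect_equal(dd[1, 2], brute)
  expect_error(rogers_distance(marker_set(
    rbind(a = c(NA, 0), b = c(2, 2)) |> `colnames<-`(c("m1", "m2")),
    tibble::tibble(marker_id = c("m1", "m2"), chrom = "chr1",
                   pos = c(1L, 2L)))), "filter")
})

test_that("rogers_distance satisfies the triangle inequality", {
  set.seed(42)
  codes <- matrix(sample(0:2, 30 * 50, replace = TRUE), 30,
                  dimnames = list(sprintf("g%02d", 1:30),
                                  sprintf("m%02d", 1:50)))
  m <- marker_set(codes, tibble::tibble(marker_id = colnames(codes),
                                        chrom = "chr1", pos = 1:50 * 100L))
  d <- rogers_distance(m)
  for (i in 1:100) {
    tri <- sample(30, 3)
    expect_lte(d[tri[1], tri[2]],
               d[tri[1], tri[3]] + d[tri[3], tri[2]] + 1e-12)
  }
})

test_that("deduplicate groups by single linkage with a canonical id", {
  d <- matrix(1, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  diag(d) <- 0
  d["a", "b"] <- d["b", "a"] <- 0.02
  d["b", "c"] <- d["c", "b"] <- 0.02
  d["a", "c"] <- d["c", "a"] <- 0.04
  map <- deduplicate(d, threshold = 0.03)
  expect_equal(unique(map$canonical_id), "a")  # transitive closure
  # no pair below threshold -> identity map
  d2 <- d; d2[upper.tri(d2)] <- 0.5; d2[lower.tri(d2)] <- 0.5
  map2 <- deduplicate(d2)
  expect_equal(map2$genotype_id, map2$canonical_id)
  # idempotent
  expect_equal(map$canonical_id,
               map$canonical_id[match(map$canonical_id, map$genotype_id)])
})

test_that("GRM formulas match a brute-force toy computation", {
  codes <- rbind(g1 = c(0, 2), g2 = c(2, 1), g3 = c(1, 0))
  colnames(codes) <- c("m1", "m2")
  m <- marker_set(codes, tibble::tibble(marker_id = c("m1", "m2"),
                                        chrom = "chr1", pos = c(1L, 2L)))
  grms <- build_grms(m)
  p <- colMeans(codes) / 2
  w <- sweep(codes, 2, 2 * p)
  expect_equal(unclass(grms$GRM_a)[1:3, 1:3],
               tcrossprod(w) / (2 * sum(p * (1 - p))),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(mean(diag(grms$GRM_aa)), 1, tolerance = 1e-6)
  # duplicate genotypes share their GRM row
  dat <- tiny_dataset()
  ga <- dat$kernels$GRM_a
  dup <- grep("_dup$", rownames(ga), value = TRUE)[1]
  src <- sub("_dup$", "", dup)
  expect_equal(ga[dup, src], ga[dup, dup], tolerance = 1e-9)
  expect_error(build_grms(toy_markers()), "Monomorphic")
})

test_that("derive_hybrid_genotypes averages parents and checks presence", {
  codes <- rbind(f = c(2, 0), m = c(2, 2))
  colnames(codes) <- c("m1", "m2")
  lines <- marker_set(codes, tibble::tibble(marker_id = c("m1", "m2"),
                                            chrom = "chr1", pos = c(1L, 2L)))
  catalog <- tibble::tibble(genotype_id = "h1", material_type = "hybrid",
                            female_parent = "f", male_parent = "m",
                            series = "Exp_1")
  hy <- derive_hybrid_genotypes(lines, catalog)
  expect_equal(unname(hy$codes["h1", ]), c(2, 1))
  catalog$male_parent <- "absent"
  expect_error(derive_hybrid_genotypes(lines, catalog), "h1")
})

test_that("pcoa recovers linear structure with deterministic signs", {
  set.seed(9)
  x <- sort(runif(20))
  d <- as.matrix(dist(x))
  rownames(d) <- colnames(d) <- paste0("p", 1:20)
  fit <- pcoa(d, k = 1)  # collinear points: a single positive eigenvalue
  expect_gt(abs(cor(fit$coordinates[, 1], x)), 0.999)
  # largest-magnitude loading is positive
  expect_gt(fit$coordinates[which.max(abs(fit$coordinates[, 1])), 1], 0)
  # duplicate entities coincide
  d2 <- as.matrix(dist(c(x, x[1])))
  rownames(d2) <- colnames(d2) <- paste0("p", 1:21)
  fit2 <- pcoa(d2, k = 1)
  expect_equal(fit2$coordinates[1, 1], fit2$coordinates[21, 1],
               tolerance = 1e-9)
  expect_warning(pcoa(d, k = 19), "positive eigenvalues")
})
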