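#' Select a genetically diverse core set
#'
#' Greedy maximization of the average entry-to-nearest-entry distance:
#' start from the pair at maximal distance, then repeatedly add the
#' genotype that maximizes the mean, over the enlarged set, of each
#' entry's distance to its nearest other entry. Deterministic given the
#' distance matrix (ties broken by id order).
#'
#' @param d symmetric genotype distance matrix (e.g. Rogers).
#' @param n core-set size.
#' @return character vector of selected genotype ids.
#' @export
select_core_set <- function(d, n = 500) {
  if (n < 2) abort("Core set size must be at least 2.")
  ids <- rownames(d)
  if (n > length(ids)) abort("Core set larger than the population.")
  if (n == length(ids)) return(ids)
  d <- unclass(d)
  ord <- order(ids)
  d <- d[ord, ord]
  ids <- ids[ord]

  start <- which(d == max(d), arr.ind = TRUE)[1, ]
  selected <- sort(c(start[[1]], start[[2]]))
  nn <- rep(d[selected[1], selected[2]], 2)  # nearest-entry dist per selected
  candidates <- setdiff(seq_along(ids), selected)
  # distance of each candidate to its nearest selected entry
  cand_nn <- pmin(d[candidates, selected[1]], d[candidates, selected[2]])

  while (length(selected) < n) {
    # objective after adding c: mean(pmin(nn, d[sel, c]), cand_nn[c])
    scores <- vapply(seq_along(candidates), function(j) {
      c_idx <- candidates[j]
      (sum(pmin(nn, d[selected, c_idx])) + cand_nn[j]) /
        (length(selected) + 1)
    }, numeric(1))
    best <- which.max(scores)
    c_idx <- candidates[best]
    nn <- c(pmin(nn, d[selected, c_idx]), cand_nn[best])
    selected <- c(selected, c_idx)
    candidates <- candidates[-best]
    if (length(candidates)) {
      cand_nn <- pmin(cand_nn[-best], d[candidates, c_idx])
    }
  }
  ids[selected]
}

#' Extract G-by-E patterns from a complete prediction matrix
#'
#' Fits `y = mu + genotype + environment + e` with genotype and
#' environment as independent random effects on the (gap-filled) predicted
#' grain-yield matrix and takes the residuals — the part of predicted
#' performance that genotype and environment main effects cannot explain.
#' Because random-effect estimates are shrunken, the raw residuals retain
#' a small remnant of the main effects; the pattern matrix removes the
#' remaining row and column means exactly, so patterns are orthogonal to
#' the genotype and environment indicator spaces.
#'
#' @param predictions complete genotype-by-environment numeric matrix.
#' @return a `gxe_pattern` matrix (same dimnames) with row/column means
#'   zero; the fitted model's variance components are in
#'   `attr(, "var_components")`.
#' @export
extract_gxe_patterns <- function(predictions) {
  if (anyNA(predictions)) {
    abort("Prediction matrix has gaps; fill them with predict() first.")
  }
  long <- tibble::tibble(
    genotype = rep(rownames(predictions), ncol(predictions)),
    environment = rep(colnames(predictions), each = nrow(predictions)),
    value = as.vector(predictions))
  fit <- lme4::lmer(value ~ 1 + (1 | genotype) + (1 | environment),
                    data = long,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular =
                                                  lme4::.makeCC("ignore",
                                                                tol = 1e-4)))
  res <- matrix(residuals(fit), nrow(predictions),
                dimnames = dimnames(predictions))
  # exact removal of residual main-effect remnants (double-centering)
  res <- sweep(res, 1, rowMeans(res))
  res <- sweep(res, 2, colMeans(res))
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(res, var_components = vc,
            class = c("gxe_pattern", class(res)))
}

silhouette_scores <- function(dmat, cluster) {
  n <- nrow(dmat)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- cluster == cluster[i]
    if (sum(own) <= 1L) { s[i] <- 0; next }
    a <- mean(dmat[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(cluster), cluster[i]), function(cl)
      mean(dmat[i, cluster == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

#' K-means clustering of environments on G-by-E patterns
#'
#' Environments are embedded by classical principal coordinates (first two
#' axes) of their Euclidean distances in G-by-E-pattern space, then
#' partitioned by K-means with multiple restarts. With `k = "auto"` the
#' number of clusters is scanned over 2..floor(n/min_size) and chosen to
#' maximize the mean silhouette subject to every cluster holding at least
#' `min_size` environments; the within-cluster SSE path is reported
#' alongside for elbow inspection.
#'
#' @param patterns a `gxe_pattern` matrix (genotypes x environments).
#' @param k number of clusters or `"auto"`.
#' @param min_size minimum environments per cluster.
#' @param nstart K-means restarts.
#' @param seed integer seed.
#' @return a `cluster_assignment`: list with `assignment` (tibble:
#'   environment, cluster), `k`, `sse`, `silhouette` (mean), `scan`
#'   (tibble over scanned k), and `coordinates`.
#' @export
cluster_gxe <- function(patterns, k = "auto", min_size = 3, nstart = 50,
                        seed = 1L) {
  envs <- colnames(patterns)
  n <- length(envs)
  if (n < 2 * min_size) abort("Too few environments for two clusters.")
  dmat <- as.matrix(dist(t(patterns)))
  coords <- pcoa(dmat, k = 2)$coordinates
  set.seed(as.integer(seed))

  run_k <- function(kk) {
    km <- kmeans(coords, centers = kk, nstart = nstart, iter.max = 100)
    sil <- mean(silhouette_scores(dmat, km$cluster))
    list(cluster = km$cluster, sse = km$tot.withinss, sil = sil,
         min_size = min(table(km$cluster)))
  }

  if (identical(k, "auto")) {
    k_max <- floor(n / min_size)
    if (k_max < 2) abort("No k satisfies the minimum cluster size.")
    scan <- lapply(2:k_max, run_k)
    scan_tbl <- tibble::tibble(
      k = 2:k_max,
      sse = vapply(scan, `[[`, 0, "sse"),
      silhouette = vapply(scan, `[[`, 0, "sil"),
      min_cluster = vapply(scan, `[[`, 0, "min_size"))
    ok <- scan_tbl$min_cluster >= min_size
    if (!any(ok)) abort("No k satisfies the minimum cluster size.")
    pick <- which(ok)[which.max(scan_tbl$silhouette[ok])]
    chosen <- scan[[pick]]
    k <- scan_tbl$k[pick]
  } else {
    if (k < 2) abort("k must be at least 2.")
    chosen <- run_k(k)
    scan_tbl <- tibble::tibble(k = k, sse = chosen$sse,
                               silhouette = chosen$sil,
                               min_cluster = chosen$min_size)
    if (chosen$min_size < min_size) {
      warn(sprintf("Cluster size %d below min_size %d at k = %d.",
                   chosen$min_size, min_size, k))
    }
  }
  structure(list(assignment = tibble::tibble(environment = envs,
                                             cluster = unname(chosen$cluster)),
                 k = k, sse = chosen$sse, silhouette = chosen$sil,
                 scan = scan_tbl, coordinates = coords),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment: k = %d, mean silhouette %.3f, SSE %.3g>\n",
              x$k, x$silhouette, x$sse))
  print(table(x$assignment$cluster))
  invisible(x)
}

#' Cophenetic correlation between two dendrograms
#'
#' Pearson correlation of the upper triangles of the two cophenetic
#' distance matrices, aligned on the shared leaf labels. Note this is
#' computed on raw merge heights: monotone but non-linear rescaling of one
#' tree's heights changes the value.
#'
#' @param tree_a,tree_b `hclust` or `env_dendrogram` objects over the same
#'   leaf set.
#' @return correlation in \[-1, 1\].
#' @export
cophenetic_correlation <- function(tree_a, tree_b) {
  cm <- function(x) {
    if (inherits(x, "env_dendrogram")) return(x$cophenetic)
    as.matrix(cophenetic(x))
  }
  a <- cm(tree_a)
  b <- cm(tree_b)
  if (!setequal(rownames(a), rownames(b))) {
    abort("Trees have different leaf sets.")
  }
  b <- b[rownames(a), rownames(a)]
  cor(upper_tri_vec(a), upper_tri_vec(b))
}

#' Environment-variable importance for G-by-E clusters
#'
#' Trains a gradient-boosted tree classifier (xgboost, multiclass softprob)
#' to predict each environment's G-by-E cluster from its 297 environment
#' variables. Reports (a) mean accuracy over a repeated stratified k-fold
#' validation study (`n_splits` folds x `n_repeats` repeats) and (b)
#' gain-based importance scores from a final model trained on an 80/20
#' train/validation split with multiclass-log-loss early stopping, scaled
#' to \[0, 1\] (`scale = "max"`) or to sum 1 (`scale = "normalize"`), plus
#' per-variable (mean over months) and per-month aggregations.
#'
#' @param ev an `ev_matrix` over the clustered environments.
#' @param clusters a `cluster_assignment` (or tibble environment/cluster).
#' @param nrounds,eta,max_depth,early_stopping_rounds booster settings;
#'   the reference protocol uses 3000 trees, learning rate 0.1, depth 30,
#'   early stopping after 100 rounds.
#' @param n_splits,n_repeats validation-study design.
#' @param scale importance scaling.
#' @param seed integer seed.
#' @return an `ev_importance` list: `accuracy` (mean over splits),
#'   `split_accuracy`, `importance` (tibble: feature, variable, month,
#'   gain, scaled), `variable_importance`, `month_importance`.
#' @export
ev_importance <- function(ev, clusters, nrounds = 3000, eta = 0.1,
                          max_depth = 30, early_stopping_rounds = 100,
                          n_splits = 5, n_repeats = 3,
                          scale = c("max", "normalize"), seed = 1L) {
  scale <- match.arg(scale)
  assign <- if (inherits(clusters, "cluster_assignment"))
    clusters$assignment else tibble::as_tibble(clusters)
  x <- unclass(ev)[assign$environment, , drop = FALSE]
  y <- as.integer(factor(assign$cluster)) - 1L
  n_class <- length(unique(y))
  tab <- table(y)
  if (any(tab < n_splits)) {
    abort(sprintf(paste0("Cluster(s) with fewer than n_splits = %d ",
                         "environments; merge clusters or lower n_splits."),
                  n_splits))
  }
  set.seed(as.integer(seed))
  params <- list(objective = "multi:softprob", num_class = n_class,
                 eta = eta, max_depth = max_depth, nthread = 1)

  # repeated stratified k-fold accuracy
  acc <- numeric(0)
  for (rep_i in seq_len(n_repeats)) {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(n_splits), length(idx))
    }
    for (f in seq_len(n_splits)) {
      tr <- fold != f
      bst <- xgboost::xgb.train(
        params = params,
        data = xgboost::xgb.DMatrix(x[tr, , drop = FALSE], label = y[tr]),
        nrounds = nrounds, verbose = 0)
      pr <- matrix(predict(bst, xgboost::xgb.DMatrix(x[!tr, , drop = FALSE])),
                   ncol = n_class, byrow = TRUE)
      acc <- c(acc, mean(max.col(pr) - 1L == y[!tr]))
    }
  }

  # final model with early stopping on an 80/20 split
  val <- sample(seq_along(y), max(1L, round(0.2 * length(y))))
  dtrain <- xgboost::xgb.DMatrix(x[-val, , drop = FALSE], label = y[-val])
  dval <- xgboost::xgb.DMatrix(x[val, , drop = FALSE], label = y[val])
  bst <- xgboost::xgb.train(
    params = c(params, list(eval_metric = "mlogloss")),
    data = dtrain, nrounds = nrounds,
    evals = list(train = dtrain, validation = dval),
    early_stopping_rounds = early_stopping_rounds, verbose = 0)

  imp <- xgboost::xgb.importance(model = bst)
  gain <- setNames(rep(0, ncol(x)), colnames(x))
  gain[imp$Feature] <- imp$Gain
  scaled <- if (scale == "max") gain / max(gain) else gain / sum(gain)
  feat <- colnames(x)
  month <- sub(".*_", "", feat)
  variable <- sub("_[^_]*$", "", feat)
  importance <- tibble::tibble(feature = feat, variable = variable,
                               month = month, gain = unname(gain),
                               scaled = unname(scaled))
  month_order <- month.abb[c(10:12, 1:8)]
  structure(list(
    accuracy = mean(acc), split_accuracy = acc,
    importance = importance,
    variable_importance = importance |>
      dplyr::group_by(.data$variable) |>
      dplyr::summarise(scaled = mean(.data$scaled), .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$scaled)),
    month_importance = importance |>
      dplyr::group_by(month = factor(.data$month, levels = month_order)) |>
      dplyr::summarise(scaled = mean(.data$scaled), .groups = "drop"),
    model = bst), class = "ev_importance")
}

#' @export
print.ev_importance <- function(x, ...) {
  cat(sprintf("<ev_importance: validation accuracy %.1f%%; top variables: %s>\n",
              100 * x$accuracy,
              paste(head(x$variable_importance$variable, 5), collapse = ", ")))
  invisible(x)
}
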