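#' Predict phenotypes from a fitted kernel mixed model
#'
#' Predictions are the posterior-mean intercept/fixed part plus the sum of
#' the posterior-mean random effects at each row's term levels. Because
#' kernels are built over all rows supplied to [build_model()] (training
#' rows carry `value`, prediction rows carry `NA`), effects for unobserved
#' levels are conditioned on the whole kernel: a genotype never seen in
#' training still receives a genomic prediction through its kernel row,
#' while under an identity kernel its effect is pure prior noise centered
#' on zero.
#'
#' @param object a `kmm_fit`.
#' @param newdata optional tibble of design rows (columns as in the spec's
#'   `pheno`); defaults to the spec rows whose `value` was `NA`. Levels
#'   absent from a term's kernel label space raise an error.
#' @param ... unused.
#' @return tibble: the design rows plus a `prediction` column.
#' @export
predict.kmm_fit <- function(object, newdata = NULL, ...) {
  spec <- object$spec
  if (is.null(newdata)) {
    rows <- which(!spec$train)
    newdata <- spec$data[rows, , drop = FALSE]
    Xn <- spec$X[rows, , drop = FALSE]
  } else {
    newdata <- tibble::as_tibble(newdata)
    mf <- stats::model.frame(spec$fixed_formula, data = newdata,
                             na.action = NULL)
    Xn <- stats::model.matrix(spec$fixed_formula, mf)
    if (ncol(Xn) != length(object$fixed)) {
      abort("Fixed-effect design of `newdata` does not match the fit.")
    }
  }
  pred <- as.vector(Xn %*% object$fixed)
  for (k in seq_along(spec$terms)) {
    term <- spec$terms[[k]]
    if (is.null(term$level_cols)) {
      abort(sprintf("Term %s has no level mapping for new rows.", term$name))
    }
    lev <- do.call(paste, c(unname(as.list(newdata[term$level_cols])),
                            sep = ":"))
    u <- object$effects[[k]]
    i <- match(lev, names(u))
    if (anyNA(i)) {
      abort(sprintf("Term %s: label(s) absent from kernel space: %s",
                    term$name,
                    paste(head(unique(lev[is.na(i)]), 5), collapse = ", ")))
    }
    pred <- pred + u[i]
  }
  dplyr::mutate(newdata, prediction = unname(pred))
}

#' Closed-form BLUP via the mixed-model equations
#'
#' Exact generalized-least-squares solution for fixed effects and best
#' linear unbiased predictions of every random term, with all variance
#' components supplied. Used as the deterministic oracle for the Gibbs
#' sampler and as a fast path when variances are known. Solves the
#' equivalent observation-space system `V = sum sigma2_t Z K Z' + R` rather
#' than inverting kernels, so singular kernels are handled.
#'
#' @param spec a `kmm_spec`.
#' @param variances named list/vector of variance components: one entry per
#'   random term name plus `"error"`.
#' @return list with `fixed` (GLS estimates), `effects` (named vectors over
#'   each term's kernel labels), and `fitted` (training-row fitted values).
#' @export
blup_oracle <- function(spec, variances) {
  stopifnot(inherits(spec, "kmm_spec"))
  need_names <- c(vapply(spec$terms, `[[`, "", "name"), "error")
  missing <- setdiff(need_names, names(variances))
  if (length(missing)) {
    abort(sprintf("Missing variance component(s): %s",
                  paste(missing, collapse = ", ")))
  }
  train <- spec$train
  y <- spec$data$value[train]
  n <- length(y)
  X <- spec$X[train, , drop = FALSE]

  if (!is.null(spec$residual_group)) {
    g <- spec$residual_group[train]
    R <- diag(vapply(g, function(gg)
      variances[[paste0("error@", gg)]] %||% variances[["error"]],
      numeric(1)), n)
  } else {
    R <- diag(variances[["error"]], n)
  }

  V <- R
  zk <- vector("list", length(spec$terms))
  for (k in seq_along(spec$terms)) {
    term <- spec$terms[[k]]
    idx <- match(term$levels, rownames(term$kernel))[train]
    C <- matrix(0, nrow(term$kernel), n)  # K Z'
    ok <- !is.na(idx)
    C[, ok] <- unclass(term$kernel)[, idx[ok], drop = FALSE]
    ZKZ <- matrix(0, n, n)
    ZKZ[ok, ] <- C[idx[ok], , drop = FALSE]
    V <- V + variances[[term$name]] * ZKZ
    zk[[k]] <- C
  }
  Vi <- tryCatch(chol2inv(chol(V)), error = function(e)
    abort(sprintf("Singular phenotypic covariance (rank issue: %s).",
                  conditionMessage(e))))
  XtVi <- crossprod(X, Vi)
  beta <- tryCatch(solve(XtVi %*% X, XtVi %*% y), error = function(e)
    abort(sprintf("Singular fixed-effect system (rank %d, %d columns).",
                  qr(X)$rank, ncol(X))))
  resid_v <- Vi %*% (y - X %*% beta)
  effects <- vector("list", length(spec$terms))
  names(effects) <- vapply(spec$terms, `[[`, "", "name")
  fitted <- as.vector(X %*% beta)
  for (k in seq_along(spec$terms)) {
    term <- spec$terms[[k]]
    u <- as.vector(variances[[term$name]] * zk[[k]] %*% resid_v)
    effects[[k]] <- setNames(u, rownames(term$kernel))
    idx <- match(term$levels, rownames(term$kernel))[train]
    fitted <- fitted + ifelse(is.na(idx), 0, u[idx])
  }
  list(fixed = setNames(as.vector(beta), colnames(X)), effects = effects,
       fitted = fitted)
}
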