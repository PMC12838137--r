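#' Relationship kernel objects
#'
#' A kernel is a labeled, symmetric, positive semi-definite relationship
#' matrix over a set of entities (genotypes, environments, years, sites, or
#' genotype-by-environment cells). Kernels are plain numeric matrices with
#' dimnames plus a `kind` attribute, so all of base R's matrix algebra
#' applies; `new_kernel()` validates symmetry and (after jitter) positive
#' semi-definiteness.
#'
#' @param values square numeric matrix with identical row/col names.
#' @param kind label such as `"GRM_a"`, `"ERM_l"`, `"GERM"`, `"identity"`.
#' @param jitter added to the diagonal when the minimum eigenvalue is below
#'   `-tol`; default 1e-8.
#' @param tol tolerance for symmetry and eigenvalue checks.
#' @return a `kernel` matrix.
#' @export
new_kernel <- function(values, kind = "kernel", jitter = 1e-8, tol = 1e-8) {
  if (!is.matrix(values) || nrow(values) != ncol(values)) {
    abort("A kernel must be a square matrix.")
  }
  labs <- rownames(values)
  if (is.null(labs) || anyDuplicated(labs) > 0L) {
    abort("Kernel row names must be present and unique.")
  }
  if (max(abs(values - t(values))) > 1e-10) {
    abort(sprintf("Kernel `%s` is not symmetric to 1e-10.", kind))
  }
  values <- (values + t(values)) / 2
  colnames(values) <- labs
  # only lift the diagonal when the spectrum genuinely dips below -tol;
  # eigenvalues in [-tol, 0) are numerical noise and are left alone so
  # normalizations (mean diagonal 1) stay exact
  ev_min <- min(eigen(values, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -tol) {
    diag(values) <- diag(values) + (abs(ev_min) + jitter)
  }
  structure(values, kind = kind, class = c("kernel", class(values)))
}

#' @export
print.kernel <- function(x, ...) {
  cat(sprintf("<kernel %s: %d x %d, mean diag %.4f>\n",
              attr(x, "kind"), nrow(x), ncol(x), mean(diag(x))))
  invisible(x)
}

#' @rdname new_kernel
#' @param labels entity identifiers.
#' @export
identity_kernel <- function(labels) {
  labels <- as.character(labels)
  new_kernel(diag(length(labels)) |> `dimnames<-`(list(labels, labels)),
             kind = "identity")
}

kernel_kind <- function(k) attr(k, "kind") %||% "kernel"

is_identity_kernel <- function(k) identical(kernel_kind(k), "identity")

#' Hadamard (cell-wise) product kernel over genotype-environment cells
#'
#' Builds the covariance of a multiplicative G-by-E interaction term:
#' the element-wise product of a row-expanded environment kernel and a
#' row-expanded genomic kernel. The expansion is done on the cells actually
#' present in the data (train and test rows), never in level space, so
#' unbalanced designs are handled. By the Schur product theorem the result
#' is positive semi-definite when both factors are.
#'
#' @param cells tibble/data.frame with the level columns named in `ids`.
#' @param kernel_a,kernel_b the two factor kernels.
#' @param ids character(2): column names in `cells` giving, for each cell,
#'   the level label in `kernel_a` and `kernel_b` respectively.
#' @param kind label for the resulting kernel.
#' @return a `kernel` over `nrow(cells)` cells labeled `a:b`.
#' @export
hadamard_kernel <- function(cells, kernel_a, kernel_b, ids, kind = "GERM") {
  la <- as.character(cells[[ids[1]]])
  lb <- as.character(cells[[ids[2]]])
  missing_a <- setdiff(unique(la), rownames(kernel_a))
  missing_b <- setdiff(unique(lb), rownames(kernel_b))
  if (length(missing_a) || length(missing_b)) {
    abort(sprintf("Labels absent from factor kernels: %s",
                  paste(head(c(missing_a, missing_b), 5), collapse = ", ")))
  }
  vals <- kernel_a[la, la, drop = FALSE] * kernel_b[lb, lb, drop = FALSE]
  cell_lab <- paste(la, lb, sep = ":")
  if (anyDuplicated(cell_lab) > 0L) abort("Duplicate cells in Hadamard expansion.")
  dimnames(vals) <- list(cell_lab, cell_lab)
  new_kernel(vals, kind = kind)
}

#' Kernel health checks
#'
#' @param k a `kernel`.
#' @param tol minimum-eigenvalue tolerance.
#' @return invisibly, a list with `symmetric`, `min_eigenvalue`, `mean_diag`.
#' @export
check_kernel <- function(k, tol = 1e-8) {
  sym <- max(abs(k - t(k))) <= 1e-10
  ev <- min(eigen(unclass(k), symmetric = TRUE, only.values = TRUE)$values)
  res <- list(symmetric = sym, min_eigenvalue = ev, mean_diag = mean(diag(k)))
  if (!sym) abort("Kernel is not symmetric.")
  if (ev < -tol) abort(sprintf("Kernel min eigenvalue %.3g below -%g.", ev, tol))
  invisible(res)
}

#' Write / read a labeled kernel as CSV
#'
#' @param k kernel matrix.
#' @param path CSV path; first column holds the row labels.
#' @export
write_kernel_csv <- function(k, path) {
  df <- data.frame(id = rownames(k), unclass(k), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kernel_csv
#' @param kind kernel kind label to attach on read.
#' @export
read_kernel_csv <- function(path, kind = "kernel") {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  new_kernel(m, kind = kind)
}
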