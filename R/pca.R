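#' Correlation-matrix PCA of Yeo-Johnson-transformed metabolites
#'
#' Transforms each metabolite with its fitted Yeo-Johnson spec, standardizes
#' (zero mean, unit variance), and eigendecomposes the correlation matrix.
#' Components with eigenvalue > 1 are retained by default (Kaiser rule);
#' loading-vector signs are fixed so the largest-magnitude entry of each
#' loading is positive. Correlation PCA is used because concentrations live
#' on very different scales, and it is the only convention under which the
#' eigenvalue > 1 retention rule is meaningful.
#'
#' @param table a `cohort_table` with complete metabolite columns, or a
#'   plain numeric matrix.
#' @param specs named list of `transform_spec` per metabolite (from
#'   [yeo_johnson_fit()]); `NULL` fits them here.
#' @param retain_k override for the number of retained components
#'   (default `NULL`: Kaiser rule).
#' @return a `pca_result`: list with `eigenvalues` (descending), `loadings`
#'   (variables x components), `scores` (samples x retained components),
#'   `retained_k`, `cum_var` (cumulative variance fraction of retained
#'   components), `specs`, `center`, `scale`.
#' @export
pca_transform <- function(table, specs = NULL, retain_k = NULL) {
  if (inherits(table, "cohort_table")) {
    M <- as.matrix(as.data.frame(table)[metabolite_names(table)])
  } else {
    M <- as.matrix(table)
  }
  if (nrow(M) < 3L) stop("need at least 3 samples for PCA")
  if (anyNA(M)) stop("missing metabolite values: impute or exclude first")
  vars <- colnames(M)
  if (is.null(vars)) vars <- colnames(M) <- paste0("V", seq_len(ncol(M)))
  if (is.null(specs)) {
    specs <- lapply(vars, function(v) yeo_johnson_fit(M[, v], name = v))
    names(specs) <- vars
  }
  Y <- vapply(vars, function(v) apply_transform(specs[[v]], M[, v]),
              numeric(nrow(M)))
  ctr <- colMeans(Y)
  scl <- apply(Y, 2L, stats::sd)
  if (any(scl == 0)) {
    stop("constant transformed variable(s): ",
         paste(vars[scl == 0], collapse = ", "))
  }
  Ys <- scale(Y, center = ctr, scale = scl)
  eg <- eigen(stats::cor(Y), symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  V <- eg$vectors
  # sign convention: largest-|loading| entry positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- vars
  colnames(V) <- paste0("PC", seq_len(ncol(V)))
  k <- if (is.null(retain_k)) sum(ev > 1) else as.integer(retain_k)
  k <- max(k, 1L)
  scores <- Ys %*% V
  structure(list(eigenvalues = ev, loadings = V,
                 scores = scores[, seq_len(k), drop = FALSE],
                 scores_full = scores,
                 retained_k = k,
                 cum_var = sum(ev[seq_len(k)]) / sum(ev),
                 specs = specs, center = ctr, scale = scl),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("Correlation PCA: %d variables, %d retained components (%.1f%% variance)\n",
              nrow(x$loadings), x$retained_k, 100 * x$cum_var))
  cat("  eigenvalues:", paste(sprintf("%.2f", utils::head(x$eigenvalues, 8)),
                              collapse = " "),
      if (length(x$eigenvalues) > 8) "..." else "", "\n")
  invisible(x)
}

#' Project new samples onto fitted principal components
#' @param pca a `pca_result`.
#' @param table cohort table or matrix with the same metabolite columns.
#' @return samples x retained-components score matrix.
#' @export
pca_project <- function(pca, table) {
  if (inherits(table, "cohort_table")) {
    M <- as.matrix(as.data.frame(table)[metabolite_names(table)])
  } else M <- as.matrix(table)
  vars <- rownames(pca$loadings)
  Y <- vapply(vars, function(v) apply_transform(pca$specs[[v]], M[, v]),
              numeric(nrow(M)))
  Ys <- scale(Y, center = pca$center, scale = pca$scale)
  (Ys %*% pca$loadings)[, seq_len(pca$retained_k), drop = FALSE]
}
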