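#' Anderson-Darling test of composite normality
#'
#' Wraps the Anderson-Darling test with estimated mean and variance,
#' small-sample modification and the standard P-value approximation.
#'
#' @param values numeric vector, at least 8 finite values.
#' @return list with `statistic` and `p.value`.
#' @export
anderson_darling_normality <- function(values) {
  x <- values[is.finite(values)]
  if (length(x) < 8L) stop("need at least 8 finite values")
  if (stats::var(x) == 0) stop("constant vector: normality test undefined")
  ad <- nortest::ad.test(x)
  list(statistic = unname(ad$statistic), p.value = ad$p.value)
}

#' Fligner-Killeen test of variance homogeneity
#'
#' Median-centred rank-based chi-squared test across groups.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2), or a
#'   numeric vector when `g` supplies group labels.
#' @param g optional group labels.
#' @return list with `statistic`, `df`, `p.value`.
#' @export
fligner_killeen <- function(groups, g = NULL) {
  if (!is.null(g)) groups <- split(groups, g)
  stopifnot(length(groups) >= 2L, all(vapply(groups, length, 0L) >= 2L))
  x <- unlist(groups, use.names = FALSE)
  if (stats::var(x) == 0) stop("all observations identical")
  lab <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  ft <- stats::fligner.test(x, lab)
  list(statistic = unname(ft$statistic), df = unname(ft$parameter),
       p.value = ft$p.value)
}

#' Games-Howell pairwise comparisons
#'
#' Pairwise mean comparisons for unequal variances and sample sizes: the
#' Welch statistic \eqn{t = (\bar x_i - \bar x_j)/\sqrt{s_i^2/n_i + s_j^2/n_j}}
#' with Welch-Satterthwaite degrees of freedom, referred to the studentized
#' range distribution with `k` groups: \eqn{P = \Pr(Q_{k,df} \ge |t|\sqrt 2)}.
#' Raw pairwise P values are reported; the studentized-range reference
#' already embeds familywise control.
#'
#' @param groups named list of numeric vectors, or numeric vector with `g`.
#' @param g optional group labels.
#' @return data frame with one row per pair: `group1`, `group2`, `diff`,
#'   `se`, `df`, `t`, `p.value`.
#' @export
games_howell <- function(groups, g = NULL) {
  if (!is.null(g)) groups <- split(groups, g)
  k <- length(groups)
  stopifnot(k >= 2L, all(vapply(groups, length, 0L) >= 2L))
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  n <- vapply(groups, length, 0L)
  m <- vapply(groups, mean, 0)
  v <- vapply(groups, stats::var, 0)
  pairs <- utils::combn(k, 2L)
  out <- lapply(seq_len(ncol(pairs)), function(c2) {
    i <- pairs[1L, c2]; j <- pairs[2L, c2]
    se2 <- v[i] / n[i] + v[j] / n[j]
    if (se2 == 0) {
      if (m[i] == m[j]) {
        return(data.frame(group1 = names(groups)[i], group2 = names(groups)[j],
                          diff = 0, se = 0, df = NA_real_, t = 0, p.value = 1,
                          stringsAsFactors = FALSE))
      }
      stop("zero variance in both members of pair ", names(groups)[i], ":",
           names(groups)[j], " with unequal means")
    }
    df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) + (v[j] / n[j])^2 / (n[j] - 1))
    tt <- (m[i] - m[j]) / sqrt(se2)
    p <- stats::ptukey(abs(tt) * sqrt(2), nmeans = k, df = df,
                       lower.tail = FALSE)
    data.frame(group1 = names(groups)[i], group2 = names(groups)[j],
               diff = m[i] - m[j], se = sqrt(se2), df = df, t = tt,
               p.value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Exact two-sided binomial test of a 50:50 split
#'
#' @param m,f the two counts (e.g. males and females).
#' @return the exact two-sided P value against proportion 0.5.
#' @export
gender_binomial_test <- function(m, f) {
  stopifnot(m + f >= 1)
  stats::binom.test(m, m + f, p = 0.5)$p.value
}

#' Kendall correlation matrix with Hochberg-adjusted significance
#'
#' Computes tie-corrected Kendall tau-b for every metabolite pair, two-sided
#' P values (exact for small tie-free samples, normal approximation
#' otherwise, as in [stats::cor.test()]), and the Hochberg step-up
#' adjustment over the single family of all `p*(p-1)/2` pairs.
#'
#' @param table a `cohort_table` or a numeric matrix of variables in
#'   columns.
#' @return a `correlation_matrix`: list with `tau`, `p`, `p_adj` matrices
#'   and `undefined` (names of constant variables, rows/columns set `NA`).
#' @export
kendall_hochberg_matrix <- function(table) {
  if (inherits(table, "cohort_table")) {
    M <- as.matrix(as.data.frame(table)[metabolite_names(table)])
  } else M <- as.matrix(table)
  if (nrow(M) < 3L) stop("need at least 3 samples")
  p <- ncol(M)
  vars <- colnames(M)
  if (is.null(vars)) vars <- colnames(M) <- paste0("V", seq_len(p))
  const <- vars[apply(M, 2L, function(x) stats::var(x) == 0)]
  tau <- matrix(NA_real_, p, p, dimnames = list(vars, vars))
  pv <- tau
  diag(tau) <- 1
  for (i in seq_len(p - 1L)) {
    for (j in seq.int(i + 1L, p)) {
      if (vars[i] %in% const || vars[j] %in% const) next
      ct <- suppressWarnings(
        stats::cor.test(M[, i], M[, j], method = "kendall"))
      tau[i, j] <- tau[j, i] <- unname(ct$estimate)
      pv[i, j] <- pv[j, i] <- ct$p.value
    }
  }
  upper <- upper.tri(pv)
  raw <- pv[upper]
  adj <- rep(NA_real_, length(raw))
  ok <- !is.na(raw)
  adj[ok] <- stats::p.adjust(raw[ok], method = "hochberg")
  padj <- pv
  padj[upper] <- adj
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  structure(list(tau = tau, p = pv, p_adj = padj, undefined = const),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  off <- x$tau[upper.tri(x$tau)]
  cat(sprintf("Kendall tau matrix: %d variables; tau range [%.3f, %.3f]\n",
              nrow(x$tau), min(off, na.rm = TRUE), max(off, na.rm = TRUE)))
  if (length(x$undefined)) {
    cat("  undefined (constant):", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}
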