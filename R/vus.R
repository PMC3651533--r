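#' Ordered marker triple
#'
#' Splits a scalar marker into the three class vectors `(x, y, z)` following
#' the declared clinical order (default H < P < C). The order is an input:
#' markers are never re-oriented automatically, so a marker decreasing along
#' the class order yields a VUS below 1/6.
#'
#' @param values numeric marker vector.
#' @param classes class labels, same length; a factor or character.
#' @param order the three class levels in increasing clinical order.
#' @return a `marker_triple`: list with `x`, `y`, `z` and `order`.
#' @export
marker_triple <- function(values, classes, order = NULL) {
  if (is.null(order)) {
    order <- if (is.factor(classes)) levels(classes) else sort(unique(as.character(classes)))
  }
  if (length(order) != 3L) stop("exactly 3 ordered classes are required")
  cl <- as.character(classes)
  if (!all(cl %in% order)) stop("class labels outside the declared order")
  sp <- split(values, factor(cl, levels = order))
  if (any(vapply(sp, length, 0L) == 0L)) stop("every class must be non-empty")
  if (anyNA(values) || any(!is.finite(values))) {
    stop("marker values must be finite and non-missing")
  }
  structure(list(x = sp[[1L]], y = sp[[2L]], z = sp[[3L]], order = order),
            class = "marker_triple")
}

# Core counting kernel: O((n1+n2+n3) log n) via sorted-vector rank lookups.
# partial: ties get 1/2 (one equality consistent with x<y<z) or 1/6 (x=y=z).
vus_xyz <- function(x, y, z, partial = TRUE) {
  xs <- sort(x); zs <- sort(z)
  n1 <- length(x); n2 <- length(y); n3 <- length(z)
  x_le <- findInterval(y, xs)                    # #{x <= y_j}
  x_lt <- findInterval(y, xs, left.open = TRUE)  # #{x <  y_j}
  z_le <- findInterval(y, zs)
  z_lt <- findInterval(y, zs, left.open = TRUE)
  a <- x_lt                 # x strictly below
  cc <- n3 - z_le           # z strictly above
  total <- sum(a * cc)
  if (partial) {
    ax <- x_le - x_lt       # x tied with y_j
    cz <- z_le - z_lt       # z tied with y_j
    total <- total + 0.5 * sum(ax * cc) + 0.5 * sum(a * cz) +
      sum(ax * cz) / 6
  }
  total / (n1 * n2 * n3)
}

#' Nonparametric VUS (volume under the ROC surface)
#'
#' Empirical probability that a random triple, one subject per ordered
#' class, is correctly ordered by the marker:
#' \deqn{\widehat{VUS} = \frac{1}{n_1 n_2 n_3} \sum_{i,j,k} w(x_i, y_j, z_k)}
#' with \eqn{w = 1} for \eqn{x < y < z}. Under `tie_rule = "partial"` a
#' triple with exactly one ordering-consistent equality (\eqn{x=y<z} or
#' \eqn{x<y=z}) scores 1/2 and a triple tie 1/6, so a constant marker scores
#' exactly the random-classifier value 1/6; under `"strict"` all ties score
#' 0. An uninformative marker has VUS 1/6, a perfect one 1.
#'
#' @param triple a [marker_triple()]; alternatively pass `x`, `y`, `z`
#'   directly.
#' @param x,y,z class-wise marker vectors (lowest, middle, highest ordered
#'   class) if `triple` is not given.
#' @param tie_rule `"partial"` (default) or `"strict"`.
#' @return the VUS estimate in `[0, 1]`.
#' @examples
#' vus_estimate(x = c(1, 2), y = c(3, 4), z = c(5, 6))  # 1: perfect
#' vus_estimate(x = c(1, 4), y = c(2, 3), z = c(5, 6))  # 0.5
#' @export
vus_estimate <- function(triple = NULL, x = NULL, y = NULL, z = NULL,
                         tie_rule = c("partial", "strict")) {
  tie_rule <- match.arg(tie_rule)
  if (is.null(triple)) triple <- list(x = x, y = y, z = z)
  with(triple, {
    if (!length(x) || !length(y) || !length(z)) stop("empty class vector")
    if (anyNA(c(x, y, z)) || any(!is.finite(c(x, y, z)))) {
      stop("marker values must be finite and non-missing")
    }
  })
  vus_xyz(triple$x, triple$y, triple$z, partial = tie_rule == "partial")
}

stratified_indices <- function(n1, n2, n3) {
  list(sample.int(n1, n1, replace = TRUE),
       sample.int(n2, n2, replace = TRUE),
       sample.int(n3, n3, replace = TRUE))
}

#' Stratified bootstrap confidence interval for the VUS
#'
#' Resamples within each class independently and forms a percentile (or
#' bias-corrected accelerated) interval of the VUS.
#'
#' @param triple a [marker_triple()].
#' @param B bootstrap replicates (default 2000).
#' @param ci_level confidence level (default 0.95).
#' @param seed integer seed.
#' @param method `"percentile"` (default) or `"bca"`.
#' @param tie_rule passed to [vus_estimate()].
#' @return a `vus_result`: list with `vus`, `ci_low`, `ci_high`, `B`,
#'   `ci_level`, `method`, `seed`, `boot` (replicate values).
#' @export
vus_bootstrap_ci <- function(triple, B = 2000L, ci_level = 0.95, seed = 1L,
                             method = c("percentile", "bca"),
                             tie_rule = c("partial", "strict")) {
  stopifnot(inherits(triple, "marker_triple"))
  method <- match.arg(method)
  tie_rule <- match.arg(tie_rule)
  partial <- tie_rule == "partial"
  x <- triple$x; y <- triple$y; z <- triple$z
  n1 <- length(x); n2 <- length(y); n3 <- length(z)
  if (min(n1, n2, n3) < 2L) stop("each class needs n >= 2 for the bootstrap")
  if (B < 100L) message("B = ", B, " is very small; interval will be unstable")
  est <- vus_xyz(x, y, z, partial)
  bt <- withr::with_seed(seed, vapply(seq_len(B), function(b) {
    ix <- stratified_indices(n1, n2, n3)
    vus_xyz(x[ix[[1L]]], y[ix[[2L]]], z[ix[[3L]]], partial)
  }, 0))
  alpha <- (1 - ci_level) / 2
  if (method == "percentile") {
    ci <- stats::quantile(bt, c(alpha, 1 - alpha), names = FALSE, type = 6)
  } else {
    ci <- bca_interval(bt, est, alpha,
                       jack = vus_jackknife(x, y, z, partial))
  }
  structure(list(vus = est, ci_low = min(ci[1L], est), ci_high = max(ci[2L], est),
                 B = as.integer(B), ci_level = ci_level, method = method,
                 tie_rule = tie_rule, seed = as.integer(seed), boot = bt),
            class = "vus_result")
}

vus_jackknife <- function(x, y, z, partial) {
  c(vapply(seq_along(x), function(i) vus_xyz(x[-i], y, z, partial), 0),
    vapply(seq_along(y), function(i) vus_xyz(x, y[-i], z, partial), 0),
    vapply(seq_along(z), function(i) vus_xyz(x, y, z[-i], partial), 0))
}

bca_interval <- function(bt, est, alpha, jack) {
  z0 <- stats::qnorm(mean(bt < est) + 0.5 * mean(bt == est))
  jm <- mean(jack)
  num <- sum((jm - jack)^3)
  den <- 6 * sum((jm - jack)^2)^1.5
  a <- if (den == 0) 0 else num / den
  if (!is.finite(z0)) return(stats::quantile(bt, c(alpha, 1 - alpha), names = FALSE))
  adj <- function(q) {
    zq <- stats::qnorm(q)
    stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  }
  stats::quantile(bt, c(adj(alpha), adj(1 - alpha)), names = FALSE, type = 6)
}

#' @export
print.vus_result <- function(x, ...) {
  cat(sprintf("VUS = %.4f  [%.4f, %.4f] (%.0f%% %s CI, B = %d)\n",
              x$vus, x$ci_low, x$ci_high, 100 * x$ci_level, x$method, x$B))
  invisible(x)
}

#' Empirical three-class ROC surface grid
#'
#' For every threshold pair `c1 <= c2` over the pooled unique marker values,
#' the true class rates are `tcr1 = F1(c1)` (fraction of the lowest class at
#' or below `c1`), `tcr2 = F2(c2) - F2(c1)`, and `tcr3 = 1 - F3(c2)`. The
#' surface's numerically integrated volume equals the triple-sum VUS for
#' tie-free data.
#'
#' @param triple a [marker_triple()].
#' @return a `roc_surface`: data frame with columns `c1`, `c2`, `tcr1`,
#'   `tcr2`, `tcr3`; thresholds kept as an attribute.
#' @export
roc_surface <- function(triple) {
  stopifnot(inherits(triple, "marker_triple"))
  thr <- sort(unique(c(triple$x, triple$y, triple$z)))
  F1 <- stats::ecdf(triple$x); F2 <- stats::ecdf(triple$y); F3 <- stats::ecdf(triple$z)
  pairs <- which(outer(seq_along(thr), seq_along(thr), "<="), arr.ind = TRUE)
  c1 <- thr[pairs[, 1L]]; c2 <- thr[pairs[, 2L]]
  out <- data.frame(c1 = c1, c2 = c2,
                    tcr1 = F1(c1),
                    tcr2 = F2(c2) - F2(c1),
                    tcr3 = 1 - F3(c2))
  structure(out, class = c("roc_surface", "data.frame"), thresholds = thr)
}

#' Numerically integrate an ROC surface grid to its volume
#'
#' Riemann sum over the empirical threshold lattice:
#' \eqn{V = \sum_{a \le b} tcr_2(t_a, t_b)\, dF_1(t_a)\, dS_3(t_b)}, where
#' \eqn{dF_1} and \eqn{dS_3} are the empirical probability masses of the
#' lowest and highest class at each threshold. For tie-free data this
#' reproduces the strict triple-sum VUS exactly.
#'
#' @param surface a `roc_surface`.
#' @return the integrated volume.
#' @export
surface_volume <- function(surface) {
  stopifnot(inherits(surface, "roc_surface"))
  thr <- attr(surface, "thresholds")
  m <- length(thr)
  ia <- match(surface$c1, thr)
  ib <- match(surface$c2, thr)
  # marginal masses from the grid's own tcr columns
  F1 <- surface$tcr1[match(thr, surface$c1)]          # rows ordered by (a, b)
  S3 <- surface$tcr3[match(thr, surface$c2)]
  dF1 <- diff(c(0, F1))
  dS3 <- -diff(c(1, S3))
  sum(surface$tcr2 * dF1[ia] * dS3[ib])
}
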