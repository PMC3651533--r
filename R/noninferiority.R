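#' Verdicts from a Delta-VUS confidence bound
#'
#' Non-inferiority holds when the lower confidence bound of
#' `VUS_candidate - VUS_reference` exceeds `-delta`; superiority when it
#' exceeds 0. Superiority therefore implies non-inferiority.
#'
#' @param ci_low lower bound of the `(100 - 2 delta)`% CI of Delta-VUS.
#' @param delta non-inferiority margin (absolute VUS difference).
#' @return list with logicals `non_inferior` and `superior`.
#' @export
delta_vus_verdict <- function(ci_low, delta) {
  stopifnot(is.finite(ci_low), delta > 0)
  list(non_inferior = ci_low > -delta, superior = ci_low > 0)
}

#' Paired bootstrap non-inferiority / superiority test on Delta-VUS
#'
#' Compares a candidate panel predictor against a reference marker measured
#' on the same subjects. `B_outer` stratified (within-class) resamples of
#' the subjects are drawn; on each resample both VUS values are computed on
#' the *same* subjects and their difference recorded. The
#' `(100 - 2 delta)`% percentile interval of the resampled differences (the
#' `(delta, 1 - delta)` quantiles; 90% for the default 5% margin) yields
#' the decision: non-inferiority if the lower bound exceeds `-delta`,
#' superiority if it exceeds 0. The optional studentized mode uses
#' `B_inner` nested resamples per outer resample to estimate the standard
#' error of each difference and forms a bootstrap-t interval instead.
#'
#' @param candidate_scores,reference_scores paired numeric vectors (same
#'   samples, same order).
#' @param classes class labels, length matching the scores.
#' @param class_order the three class levels in increasing clinical order.
#' @param delta non-inferiority margin as an absolute VUS difference
#'   (default 0.05).
#' @param B_outer outer bootstrap replicates (default 1000).
#' @param B_inner inner replicates, used only in studentized mode
#'   (default 1000).
#' @param method `"percentile"` (default) or `"studentized"`.
#' @param tie_rule passed to the VUS estimator.
#' @param seed integer seed.
#' @return a `delta_vus_decision`: list with `delta_hat`, `ci_low`,
#'   `ci_high`, `delta`, `ci_level`, `non_inferior`, `superior`,
#'   `candidate_vus`, `reference_vus`, `B_outer`, `B_inner`, `method`,
#'   `seed`, `boot` (outer differences).
#' @export
delta_vus_test <- function(candidate_scores, reference_scores, classes,
                           class_order = NULL, delta = 0.05,
                           B_outer = 1000L, B_inner = 1000L,
                           method = c("percentile", "studentized"),
                           tie_rule = c("partial", "strict"), seed = 1L) {
  method <- match.arg(method)
  tie_rule <- match.arg(tie_rule)
  partial <- tie_rule == "partial"
  if (length(candidate_scores) != length(reference_scores) ||
      length(candidate_scores) != length(classes)) {
    stop("candidate, reference and classes must be paired (equal length)")
  }
  if (!is.numeric(delta) || delta <= 0 || delta >= 0.5) {
    stop("'delta' must lie in (0, 0.5)")
  }
  if (is.null(class_order)) {
    class_order <- if (is.factor(classes)) levels(classes) else unique(as.character(classes))
  }
  if (length(class_order) != 3L) stop("exactly 3 classes are required")
  cl <- factor(as.character(classes), levels = class_order)
  if (anyNA(cl)) stop("class labels outside 'class_order'")
  idx <- split(seq_along(cl), cl)
  if (any(vapply(idx, length, 0L) < 2L)) stop("each class needs n >= 2")
  ns <- vapply(idx, length, 0L)

  vus_of <- function(scores, i1, i2, i3)
    vus_xyz(scores[i1], scores[i2], scores[i3], partial)
  cand_vus <- vus_of(candidate_scores, idx[[1L]], idx[[2L]], idx[[3L]])
  ref_vus <- vus_of(reference_scores, idx[[1L]], idx[[2L]], idx[[3L]])
  delta_hat <- cand_vus - ref_vus

  out <- withr::with_seed(seed, {
    dstar <- numeric(B_outer)
    sestar <- if (method == "studentized") numeric(B_outer) else NULL
    for (b in seq_len(B_outer)) {
      i1 <- idx[[1L]][sample.int(ns[1L], ns[1L], replace = TRUE)]
      i2 <- idx[[2L]][sample.int(ns[2L], ns[2L], replace = TRUE)]
      i3 <- idx[[3L]][sample.int(ns[3L], ns[3L], replace = TRUE)]
      dstar[b] <- vus_of(candidate_scores, i1, i2, i3) -
        vus_of(reference_scores, i1, i2, i3)
      if (method == "studentized") {
        dd <- numeric(B_inner)
        for (bi in seq_len(B_inner)) {
          j1 <- i1[sample.int(ns[1L], ns[1L], replace = TRUE)]
          j2 <- i2[sample.int(ns[2L], ns[2L], replace = TRUE)]
          j3 <- i3[sample.int(ns[3L], ns[3L], replace = TRUE)]
          dd[bi] <- vus_of(candidate_scores, j1, j2, j3) -
            vus_of(reference_scores, j1, j2, j3)
        }
        sestar[b] <- stats::sd(dd)
      }
    }
    list(dstar = dstar, sestar = sestar)
  })
  dstar <- out$dstar
  ci_level <- 1 - 2 * delta
  if (method == "percentile") {
    ci <- stats::quantile(dstar, c(delta, 1 - delta), names = FALSE, type = 6)
  } else {
    se_hat <- stats::sd(dstar)
    se0 <- pmax(out$sestar, 1e-12)
    tstat <- (dstar - delta_hat) / se0
    tq <- stats::quantile(tstat, c(delta, 1 - delta), names = FALSE, type = 6)
    ci <- c(delta_hat - tq[2L] * se_hat, delta_hat - tq[1L] * se_hat)
  }
  # a degenerate paired bootstrap (candidate == reference) has zero spread
  ci_low <- min(ci[1L], delta_hat); ci_high <- max(ci[2L], delta_hat)
  verdict <- delta_vus_verdict(ci_low, delta)
  structure(list(delta_hat = delta_hat, ci_low = ci_low, ci_high = ci_high,
                 delta = delta, ci_level = ci_level,
                 non_inferior = verdict$non_inferior,
                 superior = verdict$superior,
                 candidate_vus = cand_vus, reference_vus = ref_vus,
                 B_outer = as.integer(B_outer),
                 B_inner = if (method == "studentized") as.integer(B_inner) else 0L,
                 method = method, seed = as.integer(seed), boot = dstar),
            class = "delta_vus_decision")
}

#' @export
print.delta_vus_decision <- function(x, ...) {
  cat(sprintf("Delta-VUS = %+.4f  [%.4f, %.4f] (%.0f%% CI, margin %.2f)\n",
              x$delta_hat, x$ci_low, x$ci_high, 100 * x$ci_level, x$delta))
  cat(sprintf("  candidate VUS %.4f vs reference VUS %.4f\n",
              x$candidate_vus, x$reference_vus))
  cat("  non-inferior:", x$non_inferior, " superior:", x$superior, "\n")
  invisible(x)
}

#' Forest-plot data for Delta-VUS decisions
#'
#' Flattens decisions into a plotting table: one row per comparison plus a
#' leading reference row at Delta = 0 with the +/- delta margin bars.
#'
#' @param decisions list of `delta_vus_decision` objects.
#' @param labels character labels, one per decision.
#' @return data frame with columns `label`, `delta_hat`, `ci_low`,
#'   `ci_high`, `margin_low`, `margin_zero`, `non_inferior`, `superior`,
#'   `is_reference`.
#' @export
forest_data <- function(decisions, labels = NULL) {
  if (inherits(decisions, "delta_vus_decision")) decisions <- list(decisions)
  stopifnot(length(decisions) >= 1L,
            all(vapply(decisions, inherits, TRUE, "delta_vus_decision")))
  if (is.null(labels)) labels <- paste0("panel", seq_along(decisions))
  stopifnot(length(labels) == length(decisions))
  delta <- decisions[[1L]]$delta
  ref <- data.frame(label = "reference", delta_hat = 0,
                    ci_low = -delta, ci_high = delta,
                    margin_low = -delta, margin_zero = 0,
                    non_inferior = NA, superior = NA, is_reference = TRUE,
                    stringsAsFactors = FALSE)
  rows <- lapply(seq_along(decisions), function(i) {
    d <- decisions[[i]]
    data.frame(label = labels[i], delta_hat = d$delta_hat,
               ci_low = d$ci_low, ci_high = d$ci_high,
               margin_low = -d$delta, margin_zero = 0,
               non_inferior = d$non_inferior, superior = d$superior,
               is_reference = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(list(ref), rows))
}
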