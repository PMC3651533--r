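subset_cohort <- function(table, keep) {
  out <- as.data.frame(table)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            class = c("cohort_table", "data.frame"),
            metabolites = metabolite_names(table),
            refmarker = refmarker_name(table),
            class_order = class_order(table))
}

#' Exclude samples with non-random missing metabolite data
#'
#' Drops samples whose number of missing metabolite features exceeds a
#' threshold (e.g. insufficient sample volume leaving whole panels
#' unmeasured). The reference marker is not considered here; its sporadic
#' missingness is handled by [impute_reference_marker()].
#'
#' @param table a `cohort_table`.
#' @param max_missing_features maximum tolerated count of missing metabolite
#'   features per sample; samples above it are excluded.
#' @return the filtered table; attribute `"excluded"` records the dropped
#'   sample ids and their missing-feature counts.
#' @export
exclude_nonrandom_missing <- function(table, max_missing_features = 0L) {
  stopifnot(inherits(table, "cohort_table"))
  M <- as.matrix(as.data.frame(table)[metabolite_names(table)])
  n_miss <- rowSums(is.na(M))
  drop <- n_miss > max_missing_features
  if (any(drop)) {
    remaining <- table(factor(table$class[!drop], levels = class_order(table)))
    if (any(remaining < 2L)) {
      stop("exclusion would leave a class with fewer than 2 samples: ",
           paste(names(remaining)[remaining < 2L], collapse = ", "))
    }
  }
  out <- subset_cohort(table, !drop)
  attr(out, "excluded") <- data.frame(sample_id = table$sample_id[drop],
                                      n_missing = n_miss[drop],
                                      stringsAsFactors = FALSE)
  out
}

gelman_rubin <- function(draws) {
  # draws: iterations x chains, one imputed cell
  m <- ncol(draws); n <- nrow(draws)
  means <- colMeans(draws)
  vars <- apply(draws, 2L, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Multiple imputation of the reference marker
#'
#' Imputes missing reference-marker values by chained bootstrap regression:
#' each chain repeatedly (i) draws a bootstrap resample of the samples with
#' an observed marker, (ii) refits a linear model of the log marker on class
#' and the metabolite predictors most correlated with it, and (iii) imputes
#' each missing cell from the model prediction plus a resampled residual.
#' Chains iterate until the across-chain Gelman-Rubin statistic (R-hat) of
#' every imputed cell falls at or below `rhat_target`, or `max_iterations`
#' is reached. The final imputed value is the mean of the chain draws.
#'
#' @param table a `cohort_table` (complete metabolites).
#' @param n_chains number of imputation chains (>= 2).
#' @param rhat_target convergence target for the across-chain R-hat of every
#'   imputed cell (default 1.1).
#' @param max_iterations cap on iterations per chain.
#' @param n_predictors number of metabolite predictors (most correlated with
#'   the observed log marker) entering the imputation model besides class.
#' @param seed integer seed.
#' @return an `imputation_result`: list with the completed `table`,
#'   `n_chains`, `chain_draws` (iterations x chains x cells), `rhat` per
#'   cell, `iterations_used`, `converged`, `imputed_idx`.
#' @export
impute_reference_marker <- function(table, n_chains = 3L, rhat_target = 1.1,
                                    max_iterations = 500L, n_predictors = 3L,
                                    seed = 1L) {
  stopifnot(inherits(table, "cohort_table"), n_chains >= 2L)
  ref <- table[[refmarker_name(table)]]
  miss <- which(is.na(ref))
  if (length(miss) == nrow(table)) stop("reference marker entirely missing")
  obs <- which(!is.na(ref))
  per_class_obs <- table(factor(table$class[obs], levels = class_order(table)))
  if (any(per_class_obs == 0L)) {
    stop("need at least one observed reference-marker value per class")
  }
  res <- structure(list(table = table, n_chains = n_chains,
                        chain_draws = NULL, rhat = numeric(0),
                        iterations_used = 0L, converged = TRUE,
                        imputed_idx = integer(0)),
                   class = "imputation_result")
  if (length(miss) == 0L) return(res)

  M <- as.matrix(as.data.frame(table)[metabolite_names(table)])
  logref <- log(ref + 1)
  r <- abs(stats::cor(M[obs, , drop = FALSE], logref[obs]))
  preds <- order(-r)[seq_len(min(n_predictors, ncol(M)))]
  X <- data.frame(class = factor(as.character(table$class)),
                  log1p(M[, preds, drop = FALSE]))

  withr::with_seed(seed, {
    nm <- length(miss)
    draws <- array(NA_real_, dim = c(max_iterations, n_chains, nm))
    it <- 0L
    check_every <- 10L
    converged <- FALSE
    while (it < max_iterations) {
      it <- it + 1L
      for (ch in seq_len(n_chains)) {
        # stratified so every class level survives the resample
        boot <- unlist(lapply(split(obs, table$class[obs]),
                              function(ix) sample(ix, length(ix), replace = TRUE)),
                       use.names = FALSE)
        fit <- stats::lm(logref[boot] ~ ., data = X[boot, , drop = FALSE])
        pred <- stats::predict(fit, newdata = X[miss, , drop = FALSE])
        resid <- stats::residuals(fit)
        draws[it, ch, ] <- pred + sample(resid, nm, replace = TRUE)
      }
      if (it >= 2L * check_every && it %% check_every == 0L) {
        half <- seq.int(floor(it / 2) + 1L, it)
        rh <- vapply(seq_len(nm), function(k) gelman_rubin(draws[half, , k]), 0)
        if (all(rh <= rhat_target)) { converged <- TRUE; break }
      }
    }
    half <- seq.int(floor(it / 2) + 1L, it)
    rh <- vapply(seq_len(nm), function(k) gelman_rubin(draws[half, , k]), 0)
    imputed <- vapply(seq_len(nm), function(k) mean(draws[half, , k]), 0)
    completed <- table
    completed[[refmarker_name(table)]][miss] <- pmax(exp(imputed) - 1, 0)
    res$table <- completed
    res$chain_draws <- draws[seq_len(it), , , drop = FALSE]
    res$rhat <- rh
    res$iterations_used <- it
    res$converged <- converged || all(rh <= rhat_target)
    res$imputed_idx <- miss
  })
  if (!res$converged) {
    warning("imputation did not reach R-hat <= ", rhat_target, " within ",
            max_iterations, " iterations (max R-hat ",
            sprintf("%.3f", max(res$rhat)), ")")
  }
  res
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf(paste0("Reference-marker multiple imputation: %d cell(s), ",
                     "%d chains, %d iterations, %s\n"),
              length(x$imputed_idx), x$n_chains, x$iterations_used,
              if (x$converged) "converged" else "NOT converged"))
  if (length(x$rhat)) cat("  max R-hat:", sprintf("%.3f", max(x$rhat)), "\n")
  invisible(x)
}
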