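#' Candidate feature set for panel modelling
#'
#' Bundles a complete feature matrix, three-level class labels with a
#' declared baseline, and the forced-in features (typically the
#' conventional reference marker) that every candidate subset must contain.
#'
#' @param features numeric matrix or data frame (samples x features) with
#'   named columns; no missing values, nonzero variance.
#' @param classes class labels (3 levels).
#' @param forced_in character vector of feature names forced into every
#'   subset.
#' @param baseline baseline class for the binary decompositions (default the
#'   first level; clinically the healthy controls).
#' @param class_order the 3 levels in increasing clinical order, used for
#'   ordinal scoring.
#' @return a `candidate_set`.
#' @export
candidate_set <- function(features, classes, forced_in = character(),
                          baseline = NULL, class_order = NULL) {
  X <- as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (anyNA(X) || any(!is.finite(X))) stop("features must be complete and finite")
  v <- apply(X, 2L, stats::var)
  if (any(v == 0)) stop("zero-variance feature(s): ",
                        paste(colnames(X)[v == 0], collapse = ", "))
  if (is.null(class_order)) {
    class_order <- if (is.factor(classes)) levels(classes) else unique(as.character(classes))
  }
  if (length(class_order) != 3L) stop("exactly 3 classes are required")
  cl <- factor(as.character(classes), levels = class_order)
  if (anyNA(cl) || nlevels(droplevels(cl)) != 3L) stop("all 3 classes must be observed")
  if (is.null(baseline)) baseline <- class_order[1L]
  stopifnot(baseline %in% class_order, all(forced_in %in% colnames(X)))
  structure(list(X = X, classes = cl, forced_in = forced_in,
                 baseline = baseline, class_order = class_order),
            class = "candidate_set")
}

# ridge-stabilized logistic IRLS fallback for separated fits
ridge_logit <- function(Xm, yb, eps = 1e-2, maxit = 50L) {
  beta <- rep(0, ncol(Xm))
  pen <- diag(eps, ncol(Xm)); pen[1L, 1L] <- 0   # don't penalize intercept
  for (i in seq_len(maxit)) {
    eta <- drop(Xm %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    zv <- eta + (yb - mu) / w
    beta_new <- solve(crossprod(Xm, w * Xm) + pen, crossprod(Xm, w * zv))
    if (max(abs(beta_new - beta)) < 1e-8) { beta <- drop(beta_new); break }
    beta <- drop(beta_new)
  }
  mu <- stats::plogis(drop(Xm %*% beta))
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  dev <- -2 * sum(yb * log(mu) + (1 - yb) * log(1 - mu))
  list(coef = stats::setNames(drop(beta), colnames(Xm)), deviance = dev)
}

#' Begg-Gray binary decomposition of the multinomial logit
#'
#' Approximates a three-class multinomial logistic model by two independent
#' binary logistic regressions, one per non-baseline class against the
#' baseline, each restricted to the samples of those two classes. The total
#' deviance is the sum of the two binary deviances, and
#' `BIC = deviance + p_total * log(n_used)` with `p_total` the number of
#' free parameters across blocks and `n_used` the number of samples entering
#' the fits.
#'
#' @param candidates a [candidate_set()].
#' @param subset character vector of feature names (must be non-empty unless
#'   `allow_null = TRUE` admits the intercept-only model).
#' @param allow_null fit the intercept-only model when `subset` is empty.
#' @return a `begg_gray_fit`: list with `blocks` (named list per
#'   non-baseline class of coefficient vectors), `deviance`, `bic`,
#'   `n_used`, `subset`, `separation` flag.
#' @export
begg_gray_fit <- function(candidates, subset, allow_null = FALSE) {
  stopifnot(inherits(candidates, "candidate_set"))
  if (!length(subset) && !allow_null) stop("empty subset")
  if (!all(subset %in% colnames(candidates$X))) stop("unknown feature in subset")
  Xs <- candidates$X[, subset, drop = FALSE]
  if (length(subset) > 1L && qr(cbind(1, Xs))$rank < length(subset) + 1L) {
    stop("rank-deficient subset (collinear features): ",
         paste(subset, collapse = ", "))
  }
  base <- candidates$baseline
  others <- setdiff(candidates$class_order, base)
  blocks <- list()
  dev <- 0; n_used <- 0L; separated <- FALSE
  for (cl in others) {
    keep <- candidates$classes %in% c(base, cl)
    yb <- as.integer(candidates$classes[keep] == cl)
    Xm <- cbind(`(Intercept)` = 1, Xs[keep, , drop = FALSE])
    fit <- suppressWarnings(
      stats::glm.fit(Xm, yb, family = stats::binomial()))
    co <- stats::setNames(fit$coefficients, colnames(Xm))
    # separation: vanishing deviance or diverging standardized slopes
    slope_scale <- if (length(subset)) abs(co[-1L]) * apply(Xs[keep, , drop = FALSE], 2L, stats::sd) else 0
    if (!fit$converged || any(!is.finite(co)) || fit$deviance < 1e-6 ||
        any(slope_scale > 25)) {
      separated <- TRUE
      rf <- ridge_logit(Xm, yb)
      co <- rf$coef
      dev <- dev + rf$deviance
    } else {
      dev <- dev + fit$deviance
    }
    blocks[[cl]] <- co
    n_used <- n_used + sum(keep)
  }
  p_total <- length(others) * (1L + length(subset))
  structure(list(blocks = blocks, deviance = dev,
                 bic = dev + p_total * log(n_used),
                 n_used = n_used, subset = subset, separation = separated),
            class = "begg_gray_fit")
}

#' Bayesian model averaging over Begg-Gray multinomial fits
#'
#' Enumerates feature subsets containing the forced-in features up to
#' `max_subset_size` total features, scores each by the Begg-Gray BIC,
#' retains the subsets inside Occam's window
#' (`BIC <= min BIC + 2 log(occam_ratio)`), and weights them by
#' `exp(-BIC/2)` renormalized. Averaged coefficients are the weight-sum over
#' retained subsets with absent features contributing zero.
#'
#' @param candidates a [candidate_set()].
#' @param max_subset_size maximum total number of features in a subset,
#'   including the forced-in ones.
#' @param occam_ratio Occam's window ratio (default 20); `1` keeps only the
#'   best-BIC subset.
#' @return an `averaged_model`: list with `subsets` (data frame of subset,
#'   bic, weight), `fits`, `averaged` (named list per non-baseline class of
#'   averaged coefficient vectors over all features), `inclusion_prob`,
#'   `baseline`, `class_order`, `feature_names`.
#' @export
bma_mlogit <- function(candidates, max_subset_size = 3L, occam_ratio = 20) {
  stopifnot(inherits(candidates, "candidate_set"), occam_ratio >= 1)
  forced <- candidates$forced_in
  free <- setdiff(colnames(candidates$X), forced)
  max_extra <- max(max_subset_size - length(forced), 0L)
  subsets <- list(forced)
  for (sz in seq_len(min(max_extra, length(free)))) {
    cmb <- utils::combn(free, sz, simplify = FALSE)
    subsets <- c(subsets, lapply(cmb, function(s) c(forced, s)))
  }
  fits <- list(); keep_sets <- list()
  for (s in subsets) {
    f <- tryCatch(begg_gray_fit(candidates, s, allow_null = TRUE),
                  error = function(e) NULL)
    if (!is.null(f)) { fits[[length(fits) + 1L]] <- f; keep_sets[[length(keep_sets) + 1L]] <- s }
  }
  if (!length(fits)) stop("no candidate subset could be fitted")
  bic <- vapply(fits, `[[`, 0, "bic")
  window <- bic <= min(bic) + 2 * log(occam_ratio)
  fits <- fits[window]; keep_sets <- keep_sets[window]; bic <- bic[window]
  w <- exp(-(bic - min(bic)) / 2)
  w <- w / sum(w)
  feats <- colnames(candidates$X)
  others <- setdiff(candidates$class_order, candidates$baseline)
  averaged <- lapply(others, function(cl) {
    co <- stats::setNames(rep(0, length(feats) + 1L), c("(Intercept)", feats))
    for (i in seq_along(fits)) {
      b <- fits[[i]]$blocks[[cl]]
      co[names(b)] <- co[names(b)] + w[i] * b
    }
    co
  })
  names(averaged) <- others
  incl <- stats::setNames(vapply(feats, function(f)
    sum(w[vapply(keep_sets, function(s) f %in% s, TRUE)]), 0), feats)
  subset_labels <- vapply(keep_sets, function(s)
    if (length(s)) paste(s, collapse = "+") else "(null)", "")
  ord <- order(bic)
  structure(list(
    subsets = data.frame(subset = subset_labels[ord], bic = bic[ord],
                         weight = w[ord], stringsAsFactors = FALSE),
    fits = fits[ord],
    averaged = averaged,
    inclusion_prob = incl,
    baseline = candidates$baseline,
    class_order = candidates$class_order,
    feature_names = feats),
    class = "averaged_model")
}

#' @export
print.averaged_model <- function(x, ...) {
  cat("Bayes-averaged Begg-Gray multinomial logit\n")
  cat(sprintf("  %d subset(s) in Occam's window; top: %s (weight %.3f)\n",
              nrow(x$subsets), x$subsets$subset[1L], x$subsets$weight[1L]))
  ip <- sort(x$inclusion_prob, decreasing = TRUE)
  ip <- ip[ip > 0.01]
  cat("  inclusion probabilities:",
      paste(sprintf("%s=%.2f", names(ip), ip), collapse = ", "), "\n")
  invisible(x)
}

matrix_inv_sqrt <- function(R) {
  eg <- eigen(R, symmetric = TRUE)
  if (min(eg$values) <= 0) stop("correlation matrix not positive definite")
  eg$vectors %*% diag(1 / sqrt(eg$values), nrow(R)) %*% t(eg$vectors)
}

#' CAR-score panel model
#'
#' Correlation-adjusted marginal correlations: the class labels are encoded
#' by fixed pseudo-responses (default carcinoma 1.0, healthy 0.3,
#' pancreatitis 0.1), and the CAR scores are
#' \eqn{\omega = R_{XX}^{-1/2} r_{Xy}} with \eqn{R_{XX}} the feature
#' correlation matrix and \eqn{r_{Xy}} the marginal feature-response
#' correlations. Features are ranked by squared CAR score, the top `k` kept,
#' and an ordinary least-squares fit of the encoded response on the selected
#' features provides the scalar panel predictor. When \eqn{R_{XX}} is
#' ill-conditioned (condition number > 1e6) it is shrunk toward the identity
#' with the analytic Schafer-Strimmer intensity.
#'
#' @param candidates a [candidate_set()].
#' @param pseudo_response named numeric vector mapping each class label to
#'   its pseudo-response value.
#' @param k number of features to keep (default 2).
#' @param shrink `"auto"` (default: shrink only when ill-conditioned),
#'   `TRUE`, or `FALSE` (error on ill-conditioned input).
#' @return a `car_model`: list with `car` (signed scores), `ranking`,
#'   `selected`, `coefficients` (OLS on selected features, with intercept),
#'   `pseudo_response`, `shrinkage`.
#' @export
car_fit <- function(candidates, pseudo_response = NULL, k = 2L,
                    shrink = "auto") {
  stopifnot(inherits(candidates, "candidate_set"))
  X <- candidates$X
  if (k > ncol(X)) stop("'k' exceeds the number of features")
  if (is.null(pseudo_response)) {
    pr <- c(0.3, 0.1, 1.0)  # healthy, pancreatitis, carcinoma in class order
    names(pr) <- candidates$class_order
    pseudo_response <- pr
  }
  if (!all(levels(candidates$classes) %in% names(pseudo_response))) {
    stop("'pseudo_response' must name every class")
  }
  y <- unname(pseudo_response[as.character(candidates$classes)])
  R <- stats::cor(X)
  r_xy <- drop(stats::cor(X, y))
  kappa_R <- kappa(R, exact = TRUE)
  gamma <- 0
  if (isTRUE(shrink) || (shrink == "auto" && kappa_R > 1e6)) {
    gamma <- shrinkage_intensity(X)
    R <- (1 - gamma) * R + gamma * diag(ncol(X))
  } else if (kappa_R > 1e6) {
    stop("ill-conditioned feature correlation matrix (condition number ",
         format(kappa_R, digits = 3), "); set shrink = TRUE or \"auto\"")
  }
  car <- drop(matrix_inv_sqrt(R) %*% r_xy)
  names(car) <- colnames(X)
  ranking <- order(-car^2)
  selected <- colnames(X)[ranking[seq_len(k)]]
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X[, selected, drop = FALSE]), y)
  structure(list(car = car, ranking = colnames(X)[ranking],
                 selected = selected,
                 coefficients = stats::setNames(fit$coefficients,
                                                c("(Intercept)", selected)),
                 pseudo_response = pseudo_response,
                 shrinkage = gamma,
                 class_order = candidates$class_order),
            class = "car_model")
}

# Schafer-Strimmer analytic shrinkage intensity toward the identity target
shrinkage_intensity <- function(X) {
  n <- nrow(X)
  Xs <- scale(X)
  p <- ncol(X)
  w_bar <- crossprod(Xs) / n
  # var of each off-diagonal r_ij
  num <- 0; den <- 0
  for (i in seq_len(p - 1L)) {
    for (j in seq.int(i + 1L, p)) {
      w <- Xs[, i] * Xs[, j]
      num <- num + n / (n - 1)^3 * sum((w - mean(w))^2)
      den <- den + (sum(w) / (n - 1))^2
    }
  }
  if (den == 0) return(1)
  min(1, max(0, num / den))
}

#' @export
print.car_model <- function(x, ...) {
  cat("CAR-score panel model\n")
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  top <- utils::head(x$car[x$ranking], 5)
  cat("  top CAR scores:",
      paste(sprintf("%s=%.3f", names(top), top), collapse = ", "), "\n")
  if (x$shrinkage > 0) cat(sprintf("  correlation shrinkage: %.3f\n", x$shrinkage))
  invisible(x)
}

#' Score samples with a fitted panel model
#'
#' Reduces a fitted model to one scalar "meta-marker" per sample. For an
#' averaged multinomial model the per-class probabilities come from the
#' averaged coefficients through the multinomial inverse link and the score
#' is the expected ordinal class \eqn{\sum_c rank(c) P(c)} with ranks
#' (0, 1, 2) along the declared class order; for a CAR model the score is
#' the fitted linear predictor.
#'
#' @param model an `averaged_model` or `car_model`.
#' @param features matrix or data frame with the model's feature columns.
#' @return a `panel_predictor`: list with `score` (one value per sample) and
#'   `rule` identifier.
#' @export
score_samples <- function(model, features) {
  X <- as.matrix(features)
  if (inherits(model, "averaged_model")) {
    need <- model$feature_names
    if (!all(need %in% colnames(X))) {
      stop("missing feature columns: ",
           paste(setdiff(need, colnames(X)), collapse = ", "))
    }
    Xm <- cbind(1, X[, need, drop = FALSE])
    eta <- vapply(model$averaged, function(co) drop(Xm %*% co),
                  numeric(nrow(X)))
    if (is.null(dim(eta))) eta <- matrix(eta, nrow = 1L)
    expEta <- cbind(1, exp(eta))   # baseline first
    probs <- expEta / rowSums(expEta)
    colnames(probs) <- c(model$baseline, names(model$averaged))
    probs <- probs[, model$class_order, drop = FALSE]
    score <- drop(probs %*% (seq_along(model$class_order) - 1))
    rule <- "expected_ordinal_class"
  } else if (inherits(model, "car_model")) {
    need <- model$selected
    if (!all(need %in% colnames(X))) {
      stop("missing feature columns: ",
           paste(setdiff(need, colnames(X)), collapse = ", "))
    }
    score <- drop(cbind(1, X[, need, drop = FALSE]) %*% model$coefficients)
    rule <- "car_linear_predictor"
  } else stop("unsupported model type")
  if (any(!is.finite(score))) stop("non-finite panel scores")
  structure(list(score = unname(score), rule = rule), class = "panel_predictor")
}
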