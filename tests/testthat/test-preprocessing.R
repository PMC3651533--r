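test_that("Yeo-Johnson branches match their closed forms", {
  for (l in c(-2, -0.5, 0, 1, 1.7, 2, 3)) {
    expect_identical(yeo_johnson(0, l), 0)
  }
  x <- c(0, 0.5, 2, 10)
  expect_equal(yeo_johnson(x, 1), x)                      # identity at lambda=1
  expect_equal(yeo_johnson(-1, 2), -log(2))               # negative branch, lambda=2
  expect_equal(yeo_johnson(3, 0), log(4))                 # log branch
  expect_equal(yeo_johnson(-2, 0.5), -((3^1.5 - 1) / 1.5))
})

test_that("Yeo-Johnson is strictly increasing for every lambda", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      l <- runif(1, -5, 5)
      x <- sort(runif(50, -20, 20))
      expect_true(all(diff(yeo_johnson(x, l)) > 0),
                  info = paste("lambda =", l))
    }
  })
})

test_that("rank statistics are invariant to the Yeo-Johnson transform", {
  withr::with_seed(12, {
    x <- rlnorm(40); y <- x * exp(rnorm(40, sd = 0.3))
    tau0 <- cor(x, y, method = "kendall")
    v0 <- vus_estimate(x = x[1:13], y = x[14:26], z = x[27:40])
    for (l in c(-1, 0, 0.5, 2)) {
      expect_equal(cor(yeo_johnson(x, l), yeo_johnson(y, l), method = "kendall"),
                   tau0)
      expect_equal(vus_estimate(x = yeo_johnson(x[1:13], l),
                                y = yeo_johnson(x[14:26], l),
                                z = yeo_johnson(x[27:40], l)), v0)
    }
  })
})

test_that("profile-ML lambda agrees with the established fitter", {
  skip_if_not_installed("car")
  withr::with_seed(13, {
    x <- rlnorm(200, 3, 0.6)
    fit <- yeo_johnson_fit(x)
    oracle <- car::powerTransform(x, family = "yjPower")
    expect_equal(fit$lambda, unname(oracle$lambda), tolerance = 1e-3)
  })
  expect_error(yeo_johnson_fit(rep(2, 10)), "constant")
  expect_error(yeo_johnson_fit(c(1, 2)), "at least 3")
})

test_that("non-random missing samples are excluded with class protection", {
  cfg <- cohort_config(n_per_class = c(H = 40, P = 26, C = 40),
                       missing_rate = 0, seed = 21L)
  tab <- generate_cohort(cfg)
  expect_equal(as.data.frame(exclude_nonrandom_missing(tab)),
               as.data.frame(tab), ignore_attr = TRUE)

  # three pancreatitis samples lose their whole metabolite panel
  flagged <- which(tab$class == "P")[1:3]
  mets <- sprintf("M%02d", 1:26)
  for (v in mets) tab[[v]][flagged] <- NA_real_
  out <- exclude_nonrandom_missing(tab, max_missing_features = 0)
  expect_equal(sum(out$class == "P"), 23)
  expect_equal(nrow(out), 103)
  expect_identical(attr(out, "excluded")$sample_id, tab$sample_id[flagged])

  # dropping a whole class must error, not silently proceed
  allP <- which(tab$class == "P")
  for (v in mets) tab[[v]][allP] <- NA_real_
  expect_error(exclude_nonrandom_missing(tab, 0), "fewer than 2")
})

test_that("imputation leaves observed cells untouched and converges", {
  cfg <- cohort_config(missing_rate = 0.05, seed = 31L)
  tab <- generate_cohort(cfg)
  miss <- which(is.na(tab$refmarker))
  res <- impute_reference_marker(tab, seed = 5L)
  expect_s3_class(res, "imputation_result")
  expect_false(anyNA(res$table$refmarker))
  expect_identical(res$table$refmarker[-miss], tab$refmarker[-miss])
  expect_identical(res$imputed_idx, miss)
  expect_true(all(res$rhat > 0 & is.finite(res$rhat)))
  expect_true(res$converged)
  expect_lte(res$iterations_used, 500L)

  # no missing cells: identity result
  full <- generate_cohort(cohort_config(missing_rate = 0, seed = 31L))
  res0 <- impute_reference_marker(full, seed = 5L)
  expect_identical(res0$table, full)
  expect_length(res0$imputed_idx, 0L)
})

test_that("model-based imputation beats class-blind mean imputation", {
  # strong class-marker association so class information is worth having
  cfg <- cohort_config(n_per_class = c(H = 60, P = 60, C = 60),
                       refmarker_meanlog = c(2, 3.5, 5),
                       refmarker_sdlog = c(0.4, 0.4, 0.4),
                       missing_rate = 0, seed = 33L)
  truth <- generate_cohort(cfg)
  masked <- inject_missing(truth, 0.05, seed = 34L)
  miss <- which(is.na(masked$refmarker))
  res <- impute_reference_marker(masked, seed = 35L)
  err_model <- mean(abs(log1p(res$table$refmarker[miss]) -
                          log1p(truth$refmarker[miss])))
  err_mean <- mean(abs(log1p(mean(masked$refmarker, na.rm = TRUE)) -
                         log1p(truth$refmarker[miss])))
  expect_lt(err_model, err_mean)
})

test_that("imputation defaults follow the three-chain R-hat 1.1 protocol", {
  f <- formals(impute_reference_marker)
  expect_equal(eval(f$n_chains), 3L)
  expect_equal(eval(f$rhat_target), 1.1)
})

test_that("correlation PCA matches a direct eigendecomposition oracle", {
  withr::with_seed(41, {
    n <- 60
    S <- matrix(0.4, 5, 5); diag(S) <- 1; S[1, 2] <- S[2, 1] <- 0.8
    X <- matrix(rnorm(n * 5), n) %*% chol(S)
    colnames(X) <- paste0("V", 1:5)
    # identity transforms isolate the decomposition itself
    specs <- lapply(colnames(X), function(v)
      structure(list(lambda = 1, loglik = 0, variable = v),
                class = "transform_spec"))
    names(specs) <- colnames(X)
    res <- pca_transform(X, specs = specs)
    oracle <- eigen(cor(X), symmetric = TRUE, only.values = TRUE)$values
    expect_equal(res$eigenvalues, oracle, tolerance = 1e-10)
    expect_equal(res$retained_k, sum(oracle > 1))
    # retained scores are mutually uncorrelated
    if (res$retained_k > 1) {
      cc <- cor(res$scores)
      expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
    }
    # full-loadings reconstruction of the standardized data
    Ys <- scale(X)
    rec <- res$scores_full %*% t(res$loadings)
    expect_lt(max(abs(rec - Ys)), 1e-8)
    # sign convention
    for (j in 1:5) expect_gt(res$loadings[which.max(abs(res$loadings[, j])), j], 0)
  })
})

test_that("rank-1 data put all variance on the first component", {
  withr::with_seed(42, {
    f <- rnorm(30)
    X <- outer(f, c(1, -2, 0.5, 3))
    X <- X + 1e-8 * matrix(rnorm(120), 30)  # avoid exactly constant columns
    specs <- lapply(1:4, function(j)
      structure(list(lambda = 1, loglik = 0, variable = paste0("V", j)),
                class = "transform_spec"))
    names(specs) <- paste0("V", 1:4)
    colnames(X) <- names(specs)
    res <- pca_transform(X, specs = specs)
    expect_equal(res$eigenvalues[1], 4, tolerance = 1e-6)
    expect_lt(res$eigenvalues[2], 1e-6)
  })
})

test_that("near-identity correlation still yields a valid PCA result", {
  withr::with_seed(43, {
    X <- matrix(rnorm(500 * 6), 500)
    colnames(X) <- paste0("V", 1:6)
    res <- pca_transform(X)
    expect_true(all(abs(res$eigenvalues - 1) < 0.3))
    expect_gte(res$retained_k, 1L)
    expect_equal(sum(res$eigenvalues), 6, tolerance = 1e-8)
  })
  expect_error(pca_transform(matrix(rnorm(4), 2, 2)), "at least 3 samples")
})
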