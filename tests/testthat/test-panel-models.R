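make_candidates <- function(n = 150, signal = 1.2, p_noise = 3, seed = 1) {
  withr::with_seed(seed, {
    cls <- factor(rep(c("H", "P", "C"), length.out = n),
                  levels = c("H", "P", "C"))
    shift <- c(H = 0, P = signal / 2, C = signal)[as.character(cls)]
    noise <- matrix(rnorm(n * p_noise), n, p_noise)
    colnames(noise) <- if (p_noise) paste0("noise", seq_len(p_noise))
    X <- cbind(sig = rnorm(n) + shift, noise, ref = rnorm(n) + 0.4 * shift)
    list(cs = candidate_set(X, cls, forced_in = "ref",
                            class_order = c("H", "P", "C")),
         X = X, cls = cls)
  })
}

test_that("intercept-only Begg-Gray blocks equal the class log odds", {
  d <- make_candidates(n = 90)
  fit <- begg_gray_fit(d$cs, character(0), allow_null = TRUE)
  nH <- sum(d$cls == "H")
  for (cl in c("P", "C")) {
    expect_equal(unname(fit$blocks[[cl]]["(Intercept)"]),
                 log(sum(d$cls == cl) / nH), tolerance = 1e-8)
  }
  expect_equal(fit$bic, fit$deviance + 2 * log(fit$n_used))
})

test_that("rank-deficient subsets are rejected", {
  d <- make_candidates()
  X2 <- cbind(d$X, dup = d$X[, "sig"])
  cs <- candidate_set(X2, d$cls, forced_in = "ref",
                      class_order = c("H", "P", "C"))
  expect_error(begg_gray_fit(cs, c("sig", "dup")), "rank-deficient")
})

test_that("perfect separation is flagged and handled by a penalized fit", {
  withr::with_seed(2, {
    cls <- factor(rep(c("H", "P", "C"), each = 20), levels = c("H", "P", "C"))
    X <- cbind(sep = as.numeric(cls) * 10 + runif(60),
               ref = rnorm(60))
    cs <- candidate_set(X, cls, forced_in = "ref",
                        class_order = c("H", "P", "C"))
    fit <- begg_gray_fit(cs, c("ref", "sep"))
    expect_true(fit$separation)
    expect_true(is.finite(fit$bic))
    expect_true(all(vapply(fit$blocks, function(b) all(is.finite(b)), TRUE)))
  })
})

test_that("Begg-Gray coefficients track the full multinomial ML fit", {
  skip_if_not_installed("nnet")
  d <- make_candidates(n = 900, signal = 1.5, p_noise = 0, seed = 3)
  fit <- begg_gray_fit(d$cs, c("ref", "sig"))
  or <- nnet::multinom(cls ~ ref + sig,
                       data = data.frame(cls = d$cls, d$X),
                       trace = FALSE, maxit = 500)
  oc <- coef(or)
  for (cl in c("P", "C")) {
    for (v in c("ref", "sig")) {
      expect_equal(unname(fit$blocks[[cl]][v]), oc[cl, v], tolerance = 0.15)
    }
  }
})

test_that("single-candidate averaging returns that model with weight one", {
  d <- make_candidates(p_noise = 0)
  cs <- candidate_set(d$X[, c("sig", "ref")], d$cls, forced_in = "ref",
                      class_order = c("H", "P", "C"))
  bma <- bma_mlogit(cs, max_subset_size = 2, occam_ratio = 20)
  expect_equal(sum(bma$subsets$weight), 1)
  expect_equal(unname(bma$inclusion_prob["ref"]), 1)
  # averaged coefficients are a convex combination of at most two subsets
  expect_lte(nrow(bma$subsets), 2)
})

test_that("Occam ratio one keeps only the best-BIC subset", {
  d <- make_candidates()
  bma <- bma_mlogit(d$cs, max_subset_size = 2, occam_ratio = 1)
  expect_equal(nrow(bma$subsets), 1)
  expect_equal(bma$subsets$weight, 1)
})

test_that("posterior weights are invariant to affine feature rescaling", {
  d <- make_candidates(seed = 4)
  bma1 <- bma_mlogit(d$cs, max_subset_size = 2)
  X2 <- d$X
  X2[, "sig"] <- X2[, "sig"] * 1000 + 5
  X2[, "noise1"] <- X2[, "noise1"] / 50 - 2
  cs2 <- candidate_set(X2, d$cls, forced_in = "ref",
                       class_order = c("H", "P", "C"))
  bma2 <- bma_mlogit(cs2, max_subset_size = 2)
  expect_equal(bma1$subsets$subset, bma2$subsets$subset)
  expect_equal(bma1$subsets$weight, bma2$subsets$weight, tolerance = 1e-5)
})

test_that("pure-noise candidates collapse onto the forced-in model", {
  d <- make_candidates(signal = 0, p_noise = 4, seed = 5)
  # make ref informative so the null model is not empty of signal
  bma <- bma_mlogit(d$cs, max_subset_size = 2)
  expect_equal(bma$subsets$subset[1], "ref")
  expect_gt(bma$subsets$weight[1], 0.4)
  expect_true(all(bma$inclusion_prob[paste0("noise", 1:4)] < 0.25))
})

test_that("CAR scores equal marginal correlations for orthogonal features", {
  withr::with_seed(6, {
    n <- 80
    raw <- scale(matrix(rnorm(n * 4), n), scale = FALSE)
    Q <- qr.Q(qr(raw))          # centered orthonormal columns: cor = I
    colnames(Q) <- paste0("V", 1:4)
    cls <- factor(rep(c("H", "P", "C"), length.out = n),
                  levels = c("H", "P", "C"))
    cs <- candidate_set(Q, cls, class_order = c("H", "P", "C"))
    fit <- car_fit(cs, k = 2)
    y <- c(H = 0.3, P = 0.1, C = 1.0)[as.character(cls)]
    expect_equal(fit$car, drop(cor(Q, y)), tolerance = 1e-10)
  })
})

test_that("CAR scores match a matrix-square-root oracle", {
  withr::with_seed(7, {
    n <- 120
    S <- matrix(c(1, 0.6, 0.2, 0.6, 1, -0.3, 0.2, -0.3, 1), 3, 3)
    X <- matrix(rnorm(n * 3), n) %*% chol(S)
    colnames(X) <- c("a", "b", "c")
    cls <- factor(rep(c("H", "P", "C"), each = 40), levels = c("H", "P", "C"))
    cs <- candidate_set(X, cls, class_order = c("H", "P", "C"))
    fit <- car_fit(cs, k = 2)
    y <- c(H = 0.3, P = 0.1, C = 1.0)[as.character(cls)]
    R <- cor(X)
    sv <- svd(R)  # independent square-root route
    Rinvhalf <- sv$u %*% diag(1 / sqrt(sv$d)) %*% t(sv$v)
    oracle <- drop(Rinvhalf %*% cor(X, y))
    expect_equal(unname(fit$car), oracle, tolerance = 1e-10)
    expect_length(fit$selected, 2)
  })
})

test_that("CAR defaults encode the study pseudo-responses and panel size", {
  f <- formals(car_fit)
  expect_equal(eval(f$k), 2L)
  d <- make_candidates(seed = 8)
  fit <- car_fit(d$cs)
  expect_equal(unname(fit$pseudo_response[c("C", "H", "P")]),
               c(1.0, 0.3, 0.1))
})

test_that("panel scoring reduces models to sane scalar markers", {
  d <- make_candidates(n = 120, signal = 2, p_noise = 1, seed = 9)
  bma <- bma_mlogit(d$cs, max_subset_size = 3)
  sc <- score_samples(bma, d$X)
  expect_length(sc$score, 120)
  expect_true(all(is.finite(sc$score)))
  expect_identical(sc$rule, "expected_ordinal_class")

  # zero-coefficient model scores every sample identically
  null_model <- bma
  null_model$averaged <- lapply(null_model$averaged, function(co) co * 0)
  sc0 <- score_samples(null_model, d$X)
  expect_equal(diff(range(sc0$score)), 0)

  # a monotone single-feature model preserves the feature's VUS
  cs1 <- candidate_set(d$X[, c("sig", "ref")], d$cls,
                       class_order = c("H", "P", "C"))
  one <- bma_mlogit(candidate_set(d$X[, "sig", drop = FALSE], d$cls,
                                  forced_in = "sig",
                                  class_order = c("H", "P", "C")),
                    max_subset_size = 1)
  s1 <- score_samples(one, d$X[, "sig", drop = FALSE])$score
  ord <- order(d$X[, "sig"])
  expect_true(all(diff(s1[ord]) > 0))  # monotone map of the feature
  tr_raw <- marker_triple(d$X[, "sig"], d$cls)
  tr_mod <- marker_triple(s1, d$cls)
  expect_equal(vus_estimate(tr_mod), vus_estimate(tr_raw))
  expect_error(score_samples(bma, d$X[, 1:2]), "missing feature")
})

test_that("CAR scoring is the fitted linear predictor", {
  d <- make_candidates(seed = 10)
  fit <- car_fit(d$cs, k = 2)
  sc <- score_samples(fit, d$X)
  manual <- drop(cbind(1, d$X[, fit$selected]) %*% fit$coefficients)
  expect_equal(sc$score, unname(manual))
  expect_identical(sc$rule, "car_linear_predictor")
})
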