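#' Pipeline configuration
#'
#' Settings for the full study pipeline: simulate or load a cohort, exclude
#' non-randomly-missing samples, impute the reference marker, run the
#' descriptive battery, transform and decompose the metabolites, build the
#' panel predictors (reference alone, PCA-based averaged model,
#' concentration-based averaged model, CAR model), estimate per-feature and
#' per-predictor VUS with bootstrap CIs, and test each panel against the
#' reference for non-inferiority and superiority.
#'
#' @param simulate a [cohort_config()] (mutually exclusive with `input`).
#' @param input path to a cohort CSV (see [read_cohort()]).
#' @param class_order three class labels in increasing clinical order.
#' @param vus_B bootstrap replicates for VUS CIs.
#' @param ci_level VUS confidence level.
#' @param max_subset_size,occam_ratio model-averaging settings
#'   (see [bma_mlogit()]).
#' @param pseudo_response,car_k CAR-model settings (see [car_fit()]).
#' @param delta,B_outer,B_inner non-inferiority settings
#'   (see [delta_vus_test()]).
#' @param max_missing_features exclusion threshold
#'   (see [exclude_nonrandom_missing()]).
#' @param seed master seed; stage seeds are derived from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = cohort_config(),
                            input = NULL,
                            class_order = c("H", "P", "C"),
                            vus_B = 2000L, ci_level = 0.95,
                            max_subset_size = 3L, occam_ratio = 20,
                            pseudo_response = NULL, car_k = 2L,
                            delta = 0.05, B_outer = 1000L, B_inner = 1000L,
                            max_missing_features = 0L,
                            seed = 1L) {
  if (!is.null(input) && !is.null(simulate)) {
    stop("give exactly one of 'input' or 'simulate'")
  }
  if (is.null(input) && is.null(simulate)) stop("no cohort source configured")
  structure(list(simulate = simulate, input = input, class_order = class_order,
                 vus_B = as.integer(vus_B), ci_level = ci_level,
                 max_subset_size = as.integer(max_subset_size),
                 occam_ratio = occam_ratio,
                 pseudo_response = pseudo_response, car_k = as.integer(car_k),
                 delta = delta, B_outer = as.integer(B_outer),
                 B_inner = as.integer(B_inner),
                 max_missing_features = as.integer(max_missing_features),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

pipeline_fail <- function(stage, e) {
  stop(structure(class = c("pipeline_error", "error", "condition"),
                 list(message = sprintf("[stage:%s] %s", stage,
                                        conditionMessage(e)),
                      call = NULL, stage = stage)))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) pipeline_fail(stage, e))
}

#' Run the full panel-evaluation pipeline
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, every artifact is written
#'   there as CSV/JSON along with a manifest sufficient to re-run
#'   bit-identically.
#' @return a `pipeline_result` list with elements `cohort`, `imputation`,
#'   `descriptives`, `pairwise`, `correlation`, `pca`, `feature_vus`
#'   (per-feature VUS table with the trailing random-classifier row),
#'   `models`, `predictor_vus`, `decisions`, `forest`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  ord <- config$class_order

  cohort <- run_stage("ingest", {
    if (!is.null(config$input)) read_cohort(config$input, class_order = ord)
    else generate_cohort(config$simulate)
  })
  cohort <- run_stage("exclude",
    exclude_nonrandom_missing(cohort, config$max_missing_features))
  imput <- run_stage("impute",
    impute_reference_marker(cohort, seed = config$seed + 101L))
  tab <- imput$table
  mets <- metabolite_names(tab)
  refcol <- refmarker_name(tab)
  M <- as.matrix(as.data.frame(tab)[mets])
  ref <- tab[[refcol]]
  cls <- tab$class

  descriptives <- run_stage("stats_descriptive", {
    do.call(rbind, lapply(c(mets, refcol), function(v) {
      val <- tab[[v]]
      per <- lapply(split(val, cls), function(g) {
        q <- stats::quantile(g, c(0.5, 0.025, 0.975), names = FALSE)
        ad <- tryCatch(anderson_darling_normality(g)$p.value,
                       error = function(e) NA_real_)
        c(median = q[1L], p2.5 = q[2L], p97.5 = q[3L], ad_p = ad)
      })
      row <- data.frame(variable = v, stringsAsFactors = FALSE)
      for (cl in ord) {
        for (s in names(per[[cl]])) row[[paste(cl, s, sep = "_")]] <- per[[cl]][[s]]
      }
      row
    }))
  })

  pairwise <- run_stage("stats_pairwise", {
    do.call(rbind, lapply(c(mets, refcol), function(v) {
      groups <- split(tab[[v]], cls)
      gh <- games_howell(groups)
      fk <- fligner_killeen(groups)
      row <- data.frame(variable = v, stringsAsFactors = FALSE)
      for (i in seq_len(nrow(gh))) {
        row[[paste(gh$group1[i], gh$group2[i], sep = ":")]] <- gh$p.value[i]
      }
      row$fligner_p <- fk$p.value
      row
    }))
  })

  correlation <- run_stage("correlation", kendall_hochberg_matrix(tab))
  pca <- run_stage("pca", pca_transform(tab))

  feature_vus <- run_stage("feature_vus", {
    rows <- lapply(c(refcol, mets), function(v) {
      tr <- marker_triple(tab[[v]], cls, order = ord)
      r <- vus_bootstrap_ci(tr, B = config$vus_B, ci_level = config$ci_level,
                            seed = config$seed + 211L)
      data.frame(compound = v, vus = r$vus, ci_low = r$ci_low,
                 ci_high = r$ci_high, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[order(-out$vus), ]
    rownames(out) <- NULL
    rbind(out, data.frame(compound = "Random", vus = 1 / 6,
                          ci_low = NA_real_, ci_high = NA_real_))
  })

  models <- run_stage("models", {
    pcs <- pca$scores
    cand_pca <- candidate_set(cbind(refmarker = ref, pcs), cls,
                              forced_in = "refmarker", class_order = ord)
    cand_aa <- candidate_set(cbind(refmarker = ref, M), cls,
                             forced_in = "refmarker", class_order = ord)
    cand_car <- candidate_set(cbind(refmarker = ref, M), cls,
                              class_order = ord)
    list(pca_bma = bma_mlogit(cand_pca, config$max_subset_size,
                              config$occam_ratio),
         aa_bma = bma_mlogit(cand_aa, config$max_subset_size,
                             config$occam_ratio),
         car = car_fit(cand_car, pseudo_response = config$pseudo_response,
                       k = config$car_k),
         feature_frames = list(pca = cbind(refmarker = ref, pcs),
                               aa = cbind(refmarker = ref, M)))
  })

  scores <- run_stage("scoring", {
    list(reference = ref,
         PCA = score_samples(models$pca_bma, models$feature_frames$pca)$score,
         AA = score_samples(models$aa_bma, models$feature_frames$aa)$score,
         CAR = score_samples(models$car, models$feature_frames$aa)$score)
  })

  predictor_vus <- run_stage("predictor_vus", {
    do.call(rbind, lapply(names(scores), function(nm) {
      tr <- marker_triple(scores[[nm]], cls, order = ord)
      r <- vus_bootstrap_ci(tr, B = config$vus_B, ci_level = config$ci_level,
                            seed = config$seed + 307L)
      data.frame(predictor = nm, vus = r$vus, ci_low = r$ci_low,
                 ci_high = r$ci_high, stringsAsFactors = FALSE)
    }))
  })

  decisions <- run_stage("noninferiority", {
    panels <- setdiff(names(scores), "reference")
    out <- lapply(seq_along(panels), function(i) {
      delta_vus_test(scores[[panels[i]]], scores$reference, cls,
                     class_order = ord, delta = config$delta,
                     B_outer = config$B_outer, B_inner = config$B_inner,
                     seed = config$seed + 401L + i)
    })
    names(out) <- panels
    out
  })

  forest <- run_stage("forest", forest_data(decisions, names(decisions)))

  manifest <- list(
    package = "vuspanel",
    seed = config$seed,
    class_order = ord,
    n_samples = nrow(tab),
    n_per_class = as.list(table(cls)),
    settings = list(vus_B = config$vus_B, ci_level = config$ci_level,
                    max_subset_size = config$max_subset_size,
                    occam_ratio = config$occam_ratio,
                    car_k = config$car_k, delta = config$delta,
                    B_outer = config$B_outer, B_inner = config$B_inner,
                    max_missing_features = config$max_missing_features),
    simulate = if (is.null(config$input)) unclass_config(config$simulate) else NULL,
    input = config$input,
    imputation = list(n_imputed = length(imput$imputed_idx),
                      iterations_used = imput$iterations_used,
                      converged = imput$converged,
                      max_rhat = if (length(imput$rhat)) max(imput$rhat) else NA),
    pca = list(retained_k = pca$retained_k, cum_var = pca$cum_var)
  )

  res <- structure(list(cohort = tab, imputation = imput,
                        descriptives = descriptives, pairwise = pairwise,
                        correlation = correlation, pca = pca,
                        feature_vus = feature_vus, models = models,
                        scores = scores,
                        predictor_vus = predictor_vus, decisions = decisions,
                        forest = forest, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_bundle(res, out_dir)
  res
}

unclass_config <- function(cfg) unclass(cfg)

write_bundle <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.csv(df, file.path(out_dir, name),
                                           row.names = FALSE, na = "")
  write_cohort(res$cohort, file.path(out_dir, "cohort.csv"))
  w(res$descriptives, "descriptives.csv")
  w(res$pairwise, "pairwise_p.csv")
  w(as.data.frame(res$correlation$tau), "kendall_tau.csv")
  w(as.data.frame(res$correlation$p_adj), "hochberg_p.csv")
  w(res$feature_vus, "feature_vus.csv")
  w(res$predictor_vus, "predictor_vus.csv")
  w(res$forest, "forest.csv")
  for (nm in names(res$decisions)) {
    tr <- marker_triple(res$scores[[nm]], res$cohort$class,
                        order = class_order(res$cohort))
    w(as.data.frame(roc_surface(tr)), paste0("roc_surface_", nm, ".csv"))
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Three-class panel evaluation pipeline\n")
  cat(sprintf("  cohort: %d samples (%s)\n", nrow(x$cohort),
              paste(sprintf("%s=%d", names(table(x$cohort$class)),
                            as.integer(table(x$cohort$class))), collapse = ", ")))
  cat(sprintf("  PCA: %d components retained (%.1f%% variance)\n",
              x$pca$retained_k, 100 * x$pca$cum_var))
  cat("  predictor VUS:\n")
  for (i in seq_len(nrow(x$predictor_vus))) {
    cat(sprintf("    %-9s %.4f [%.4f, %.4f]\n", x$predictor_vus$predictor[i],
                x$predictor_vus$vus[i], x$predictor_vus$ci_low[i],
                x$predictor_vus$ci_high[i]))
  }
  for (nm in names(x$decisions)) {
    d <- x$decisions[[nm]]
    cat(sprintf("  %-4s Delta-VUS %+.4f [%.4f, %.4f]  non-inferior: %s, superior: %s\n",
                nm, d$delta_hat, d$ci_low, d$ci_high, d$non_inferior, d$superior))
  }
  invisible(x)
}
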