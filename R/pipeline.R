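#' Default pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis: simulation parameters
#' (design, ROIs, ground-truth couplings), permutation and significance
#' settings, lag floor, and which ROIs get the (costly) image-specificity
#' analyses. All downstream randomness is streamed from `seed`.
#'
#' @param seed master integer seed.
#' @param n_permutations permutations for every permutation test.
#' @param alpha significance threshold.
#' @param bonferroni_m number of tests for Bonferroni adjustment of the
#'   per-ROI model p-values (default: number of ROIs).
#' @param floor_seconds interval floor before log-lags.
#' @param final_test_gap_s gap between last trial and final test, seconds.
#' @param n_novel novel images per participant in the final test.
#' @param design a [design_params()] object.
#' @param rois list of [roi_spec()].
#' @param truth a [truth_params()] object.
#' @param specificity_rois ROI names to run the image-specificity analyses on.
#' @param conservative_p use add-one permutation p-values if `TRUE`.
#' @return Config list of class `reinstatr_config`.
#' @export
default_config <- function(seed = 1L, n_permutations = 1000L, alpha = 0.05,
                           bonferroni_m = NULL, floor_seconds = 1,
                           final_test_gap_s = 172800, n_novel = 50L,
                           design = design_params(), rois = default_rois(),
                           truth = truth_params(),
                           specificity_rois = "CA1",
                           conservative_p = FALSE) {
  abort_if(n_permutations < 1L, "n_permutations must be >= 1")
  abort_if(alpha <= 0 || alpha >= 1, "alpha must lie in (0, 1)")
  roi_names <- vapply(rois, `[[`, character(1), "roi_name")
  abort_if(!all(specificity_rois %in% roi_names),
           "specificity_rois must name configured ROIs")
  structure(list(seed = as.integer(seed),
                 n_permutations = as.integer(n_permutations),
                 alpha = alpha,
                 bonferroni_m = if (is.null(bonferroni_m)) length(rois)
                                else as.integer(bonferroni_m),
                 floor_seconds = floor_seconds,
                 final_test_gap_s = final_test_gap_s,
                 n_novel = as.integer(n_novel),
                 design = design, rois = rois, truth = truth,
                 specificity_rois = specificity_rois,
                 conservative_p = conservative_p),
            class = "reinstatr_config")
}

lag_terms <- c("lag0", "lag1", "lag2", "lag3")

fit_block <- function(fit, term) {
  co <- fit$coefficients[fit$coefficients$term == term, , drop = FALSE]
  list(beta = co$estimate, se = co$se, ci = c(co$ci_lower, co$ci_upper),
       p = co$p, converged = fit$converged, n_obs = fit$n_obs)
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (unless `data` supplies `events`, `store`, `final_test`),
#' behavioral scoring, per-ROI exposure-pair similarity, high/low permutation
#' tests (mean and per pair), mixed-model inference (precision and confidence
#' models, per-pair models, likelihood-ratio comparison for adding E1-E2, and
#' a confidence-covariate control model), image-specificity analyses on the
#' configured ROIs, and report assembly. Deterministic given the config: one
#' master seed streams every stage.
#'
#' @param config a [default_config()] list.
#' @param data optional list with `events`, `store`, `final_test` (and
#'   optionally `truth`) to analyze instead of simulating.
#' @param out_dir optional directory; when given, intermediate tables
#'   (events.tsv, final_test.tsv, scored.tsv, similarity.tsv,
#'   specificity.tsv) and report.json are written there.
#' @return Report list of class `reinstatr_report`.
#' @export
run_pipeline <- function(config = default_config(), data = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "reinstatr_config"))
  seed <- config$seed
  if (is.null(data)) {
    sim <- simulate_experiment(config$design, config$rois, config$truth,
                               seed = derive_seed(seed, 10L),
                               n_novel = config$n_novel)
  } else {
    for (nm in c("events", "store", "final_test")) {
      abort_if(is.null(data[[nm]]),
               sprintf("stage 'input': missing upstream artifact '%s'", nm))
    }
    sim <- data
  }
  events <- sim$events
  store <- sim$store
  final_test <- sim$final_test
  roi_names <- store$roi_names

  # ---- behavior --------------------------------------------------------
  scored <- score_behavior(final_test, events,
                           final_test_gap_s = config$final_test_gap_s,
                           floor_seconds = config$floor_seconds)
  recog <- recognition_summary(final_test)
  chance <- lapply(split(scored, scored$participant_id), function(d) {
    participant_chance_test(d$est_rank, d$act_rank,
                            n_perm = config$n_permutations,
                            seed = derive_seed(seed, 20L +
                                match(d$participant_id[1L],
                                      sort(unique(scored$participant_id)))),
                            conservative = config$conservative_p)
  })
  accuracy <- fit_accuracy_model(scored)

  # ---- rsa + inference per ROI ----------------------------------------
  labels <- scored[, c("participant_id", "image_id", "precision_label")]
  roi_blocks <- list()
  sims <- list()
  for (k in seq_along(roi_names)) {
    roi <- roi_names[[k]]
    sim_tab <- exposure_similarities(events, store, roi,
                                     images = unique(scored$image_id))
    sims[[roi]] <- sim_tab
    hl <- list()
    for (pair in c("mean", "z12", "z23", "z13")) {
      hl[[pair]] <- high_low_permutation(
        sim_tab, labels, pair = pair, n_perm = config$n_permutations,
        seed = derive_seed(seed, 100L + 10L * k + match(
          pair, c("mean", "z12", "z23", "z13"))))
    }
    tab <- merge_tibble(scored, sim_tab[, c("participant_id", "image_id",
                                            "mean_z", "z12", "z23", "z13")],
                        by = c("participant_id", "image_id"))
    tab_mean <- tab[!is.na(tab$mean_z), , drop = FALSE]
    m_prec <- fit_mixed_logistic(tab_mean, "precision",
                                 c("mean_z", lag_terms))
    m_conf <- fit_mixed_linear(tab_mean, "confidence",
                               c("mean_z", lag_terms))
    m_cov <- fit_mixed_logistic(tab_mean, "precision",
                                c("mean_z", "confidence", lag_terms))
    tab_pairs <- tab[!is.na(tab$z12) & !is.na(tab$z23) & !is.na(tab$z13), ,
                     drop = FALSE]
    m_pairs <- fit_mixed_logistic(tab_pairs, "precision",
                                  c("z12", "z23", "z13", lag_terms))
    m_red <- fit_mixed_logistic(tab_pairs, "precision",
                                c("z23", "z13", lag_terms))
    lrt_add12 <- likelihood_ratio(m_pairs, m_red)
    m_pairs_conf <- fit_mixed_linear(tab_pairs, "confidence",
                                     c("z12", "z23", "z13", lag_terms))
    roi_blocks[[roi]] <- list(
      high_low = lapply(hl, function(x)
        list(observed = x$observed_stat, p = x$p_value)),
      precision_model = fit_block(m_prec, "mean_z"),
      confidence_model = fit_block(m_conf, "mean_z"),
      precision_model_confidence_covariate = fit_block(m_cov, "mean_z"),
      pair_models = list(
        precision = lapply(c(z12 = "z12", z23 = "z23", z13 = "z13"),
                           function(tm) fit_block(m_pairs, tm)),
        confidence = lapply(c(z12 = "z12", z23 = "z23", z13 = "z13"),
                            function(tm) fit_block(m_pairs_conf, tm))),
      lrt_add_e1e2 = list(chi2 = lrt_add12$chi2, df = lrt_add12$df,
                          p = lrt_add12$p))
  }

  # Bonferroni bookkeeping across ROIs for the headline tests
  m <- config$bonferroni_m
  hl_raw <- vapply(roi_blocks, function(b) b$high_low$mean$p, numeric(1))
  prec_raw <- vapply(roi_blocks, function(b) b$precision_model$p, numeric(1))
  adjusted <- list(
    high_low_mean = as.list(setNames(bonferroni_adjust(hl_raw, m),
                                     names(roi_blocks))),
    precision_model = as.list(setNames(bonferroni_adjust(prec_raw, m),
                                       names(roi_blocks))))

  # ---- specificity -----------------------------------------------------
  spec_blocks <- list()
  spec_tables <- list()
  for (roi in config$specificity_rois) {
    null_res <- shuffled_mapping_null(
      scored, events, store, roi, n_perm = config$n_permutations,
      seed = derive_seed(seed, 300L + match(roi, roi_names)),
      floor_seconds = config$floor_seconds)
    st <- specificity_scores(events, final_test, store, roi,
                             targets = scored[, c("participant_id",
                                                  "image_id")])
    spec_tables[[roi]] <- st
    foil_fit <- fit_specificity_model(st, scored)
    spec_blocks[[roi]] <- list(
      shuffled_mapping = list(observed_beta = null_res$observed_stat,
                              p = null_res$p_value,
                              null_q95 = unname(
                                quantile(null_res$null_values, 0.95))),
      foil_difference_model = fit_block(foil_fit, "difference"),
      n_targets = nrow(st),
      n_zero_foil_excluded = attr(st, "n_excluded"))
  }

  report <- structure(list(
    behavioral = list(
      recognition = list(
        per_participant = recog$per_participant,
        paired_t = recog$paired_t,
        anova = recog$anova),
      chance_tests = lapply(chance, function(x)
        list(observed_mean_error = x$observed_stat, p = x$p_value)),
      accuracy_model = fit_block(accuracy, "act_rank"),
      n_analysis_images = as.list(table(scored$participant_id))),
    rois = roi_blocks,
    bonferroni_adjusted = adjusted,
    specificity = spec_blocks,
    provenance = list(seed = seed,
                      n_permutations = config$n_permutations,
                      alpha = config$alpha,
                      bonferroni_m = m,
                      p_value_tags = paste(
                        "all p-values raw proportions unless listed under",
                        "bonferroni_adjusted"),
                      package_version =
                        as.character(utils::packageVersion("reinstatr")))),
    class = "reinstatr_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_events(events, file.path(out_dir, "events.tsv"))
    write_final_test(final_test, file.path(out_dir, "final_test.tsv"))
    utils::write.table(scored, file.path(out_dir, "scored.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(do.call(rbind, sims),
                       file.path(out_dir, "similarity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (length(spec_tables) > 0L) {
      st_all <- do.call(rbind, Map(function(tb, roi) {
        tb$roi <- roi; tb
      }, spec_tables, names(spec_tables)))
      utils::write.table(st_all, file.path(out_dir, "specificity.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(strip_tibbles(unclass(report)),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# jsonlite handles data frames natively; convert tibbles to plain frames
strip_tibbles <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) return(lapply(x, strip_tibbles))
  x
}

#' @export
print.reinstatr_report <- function(x, ...) {
  cat("reinstatr pipeline report\n")
  cat(sprintf("  participants: %d, analysis images: %s\n",
              nrow(x$behavioral$recognition$per_participant),
              paste(unlist(x$behavioral$n_analysis_images),
                    collapse = "/")))
  cat(sprintf("  accuracy slope: %.3f (p = %.3g)\n",
              x$behavioral$accuracy_model$beta,
              x$behavioral$accuracy_model$p))
  for (roi in names(x$rois)) {
    b <- x$rois[[roi]]
    cat(sprintf(
      "  %s: high-low p = %.3g; precision beta = %.3f (p = %.3g); confidence beta = %.3f (p = %.3g)\n",
      roi, b$high_low$mean$p, b$precision_model$beta, b$precision_model$p,
      b$confidence_model$beta, b$confidence_model$p))
  }
  for (roi in names(x$specificity)) {
    s <- x$specificity[[roi]]
    cat(sprintf(
      "  %s specificity: shuffled-mapping p = %.3g; foil-difference beta = %.3f (p = %.3g)\n",
      roi, s$shuffled_mapping$p, s$foil_difference_model$beta,
      s$foil_difference_model$p))
  }
  invisible(x)
}
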