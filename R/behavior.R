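#' Midrank transform of timeline positions
#'
#' Converts raw positions (estimated or actual) to ranks within a participant,
#' averaging ranks over ties. Ranking removes monotone response biases such as
#' compression toward the center of the timeline.
#'
#' @param values numeric vector (one participant), length >= 2, finite.
#' @return Midranks in `[1, n]` summing to `n(n+1)/2`.
#' @export
rank_transform <- function(values) {
  abort_if(length(values) < 2L, "need at least 2 values to rank")
  abort_if(!all(is.finite(values)), "values must be finite")
  rank(values, ties.method = "average")
}

#' Item-wise temporal memory error
#'
#' Absolute difference between ranked estimated and ranked actual temporal
#' positions, elementwise and aligned by image.
#'
#' @param est_ranks,act_ranks equal-length aligned rank vectors.
#' @return Non-negative error vector in rank units.
#' @export
temporal_error <- function(est_ranks, act_ranks) {
  abort_if(length(est_ranks) != length(act_ranks),
           "est_ranks and act_ranks must have equal length (aligned by image)")
  abs(est_ranks - act_ranks)
}

#' Label temporal-memory precision by participant-wise median split
#'
#' Errors strictly below the participant's median are labelled `"high"`
#' (high precision); errors at or above the median are `"low"`. If every error
#' is identical the split is degenerate: all items are labelled `"low"` with a
#' warning.
#'
#' @param errors numeric temporal errors for one participant (>= 4 values).
#' @return Character vector of `"high"`/`"low"` labels.
#' @export
label_precision <- function(errors) {
  abort_if(length(errors) < 4L, "need at least 4 errors for a median split")
  med <- median(errors)
  if (all(errors == errors[1L])) {
    warning("all temporal errors identical; degenerate split, all 'low'")
    return(rep("low", length(errors)))
  }
  ifelse(errors < med, "high", "low")
}

#' Per-participant permutation test of temporal-memory chance level
#'
#' The observed statistic is the mean temporal error. The null distribution is
#' built by shuffling the estimated ranks across images and recomputing the
#' mean error; the p-value is the proportion of null means at or below the
#' observed mean (lower error = better-than-chance memory).
#'
#' @param est_ranks,act_ranks aligned rank vectors (>= 5 images).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param conservative if `TRUE` use the add-one (never-zero) p convention.
#' @return A `reinstatr_perm` object (observed statistic, null vector,
#'   proportion p, direction, seed).
#' @export
participant_chance_test <- function(est_ranks, act_ranks, n_perm = 1000L,
                                    seed = 1L, conservative = FALSE) {
  abort_if(length(est_ranks) != length(act_ranks),
           "est_ranks and act_ranks must be aligned")
  n <- length(est_ranks)
  abort_if(n < 5L, "need at least 5 images for the chance test")
  if (n_perm < 100L) warning("fewer than 100 permutations; p is coarse")
  observed <- mean(abs(est_ranks - act_ranks))
  null_values <- with_seed(seed, {
    vapply(seq_len(n_perm),
           function(b) mean(abs(est_ranks[sample.int(n)] - act_ranks)),
           numeric(1))
  })
  new_permutation_result(observed, null_values, direction = "le",
                         n_perm = n_perm, seed = seed,
                         conservative = conservative)
}

#' Temporal lags of each image, in natural-log seconds
#'
#' For every image with three exposures: lag0 is the interval from the start
#' of the continuous-recognition phase (the participant's first trial) to E1,
#' lag1 from E1 to E2, lag2 from E2 to E3, and lag3 from E3 to the final
#' memory test. Intervals are floored at `floor_seconds` before taking the
#' natural logarithm, so the first trial of the experiment has lag0 = 0.
#'
#' @param events event table (one or more participants).
#' @param final_test_onset seconds from experiment start to the final test; a
#'   single value or a named vector by participant. Must postdate every E3.
#' @param image_id optional subset of image ids.
#' @param floor_seconds lower bound applied to intervals before the log.
#' @return Tibble with `participant_id`, `image_id`, `lag0`..`lag3`.
#' @export
compute_lags <- function(events, final_test_onset, image_id = NULL,
                         floor_seconds = 1) {
  stopifnot(is.data.frame(events))
  ev <- events[!events$is_filler, , drop = FALSE]
  if (!is.null(image_id)) ev <- ev[ev$image_id %in% image_id, , drop = FALSE]
  flog <- function(x) log(pmax(x, floor_seconds))
  out <- lapply(split(ev, ev$participant_id), function(d) {
    start <- min(events$onset[events$participant_id == d$participant_id[1L]])
    fin <- if (length(final_test_onset) > 1L)
      final_test_onset[[d$participant_id[1L]]] else final_test_onset
    by_img <- split(d, d$image_id)
    on <- t(vapply(by_img, function(x) {
      abort_if(nrow(x) != 3L,
               sprintf("image %s has %d exposures, expected 3",
                       x$image_id[1L], nrow(x)))
      o <- x$onset[order(x$exposure)]
      abort_if(is.unsorted(o, strictly = TRUE),
               sprintf("exposures of image %s are not chronological",
                       x$image_id[1L]))
      o
    }, numeric(3)))
    abort_if(any(fin <= on[, 3L]),
             "final_test_onset must postdate every third exposure")
    tibble::tibble(participant_id = d$participant_id[1L],
                   image_id = names(by_img),
                   lag0 = unname(flog(on[, 1L] - start)),
                   lag1 = unname(flog(on[, 2L] - on[, 1L])),
                   lag2 = unname(flog(on[, 3L] - on[, 2L])),
                   lag3 = unname(flog(fin - on[, 3L])))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# z-transform of a hit/FA rate with the standard 1/(2N) extreme-rate correction
corrected_z <- function(rate, n) {
  qnorm(pmin(pmax(rate, 1 / (2 * n)), 1 - 1 / (2 * n)))
}

#' Recognition-memory summary: hit/FA rates, d-prime, group tests
#'
#' Hits are old images with confidence >= 4; false alarms are novel images
#' with confidence >= 4. d' = z(hit) - z(FA), with rates of 0 or 1 replaced by
#' 1/(2N) and 1 - 1/(2N). d' is also computed within confidence bins
#' (default low = \{3,4\}, medium = \{2,5\}, high = \{1,6\}), conditioning each
#' bin's rates on responses falling in that bin. Group-level inference: a
#' two-tailed paired t-test of hit vs FA rates with Cohen's d, and a one-way
#' repeated-measures ANOVA of d' across confidence bins with eta-squared.
#'
#' @param final_test final-test table with old and novel items.
#' @param confidence_bins named list mapping bin labels to confidence values.
#' @return List with `per_participant` (tibble), `by_confidence` (tibble),
#'   `paired_t` (t, df, p, cohens_d, ci), `anova` (F, df, p, eta_sq).
#' @export
recognition_summary <- function(final_test,
                                confidence_bins = list(low = c(3, 4),
                                                       medium = c(2, 5),
                                                       high = c(1, 6))) {
  stopifnot(is.data.frame(final_test))
  abort_if(!all(final_test$confidence %in% 1:6),
           "confidence responses must lie in 1..6")
  per <- list()
  bins <- list()
  for (pid in unique(final_test$participant_id)) {
    d <- final_test[final_test$participant_id == pid, , drop = FALSE]
    old <- d[d$item_type == "old", , drop = FALSE]
    new <- d[d$item_type == "novel", , drop = FALSE]
    if (nrow(old) == 0L || nrow(new) == 0L) {
      warning(sprintf("participant %s lacks old or novel items; excluded",
                      pid))
      next
    }
    hit <- mean(old$confidence >= 4)
    fa <- mean(new$confidence >= 4)
    per[[pid]] <- tibble::tibble(
      participant_id = pid, hit_rate = hit, fa_rate = fa,
      d_prime = corrected_z(hit, nrow(old)) - corrected_z(fa, nrow(new)))
    for (b in names(confidence_bins)) {
      sel <- confidence_bins[[b]]
      ob <- old$confidence[old$confidence %in% sel]
      nb <- new$confidence[new$confidence %in% sel]
      dp <- if (length(ob) == 0L || length(nb) == 0L) NA_real_ else
        corrected_z(mean(ob >= 4), length(ob)) -
        corrected_z(mean(nb >= 4), length(nb))
      bins[[paste(pid, b)]] <- tibble::tibble(participant_id = pid,
                                              bin = b, d_prime = dp)
    }
  }
  per <- do.call(rbind, per)
  bins <- do.call(rbind, bins)
  diffs <- per$hit_rate - per$fa_rate
  if (nrow(per) < 2L || sd(diffs) == 0) {
    # degenerate group data (identical differences): no paired test possible
    paired_t <- list(t = NA_real_, df = NA_real_, p = NA_real_,
                     cohens_d = NA_real_, ci = c(NA_real_, NA_real_))
  } else {
    tt <- t.test(per$hit_rate, per$fa_rate, paired = TRUE)
    paired_t <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                     p = tt$p.value, cohens_d = mean(diffs) / sd(diffs),
                     ci = as.numeric(tt$conf.int))
  }
  bins$bin <- factor(bins$bin, levels = names(confidence_bins))
  cc <- bins[complete.cases(bins), , drop = FALSE]
  anova_res <- if (length(unique(cc$bin)) < 2L ||
                   length(unique(cc$participant_id)) < 2L) {
    # fewer than two bins or participants with data: no within-subject test
    list(F = NA_real_, df = c(NA_real_, NA_real_), p = NA_real_,
         eta_sq = NA_real_)
  } else {
    fit <- aov(d_prime ~ bin + Error(factor(participant_id)), data = cc)
    tab <- summary(fit)[["Error: Within"]][[1L]]
    list(F = tab["bin", "F value"],
         df = c(tab["bin", "Df"], tab["Residuals", "Df"]),
         p = tab["bin", "Pr(>F)"],
         eta_sq = tab["bin", "Sum Sq"] /
           (tab["bin", "Sum Sq"] + tab["Residuals", "Sum Sq"]))
  }
  list(per_participant = per, by_confidence = bins,
       paired_t = paired_t, anova = anova_res)
}

#' Mixed-effects regression of estimated on actual temporal position
#'
#' Fits `est_rank ~ act_rank` with per-participant random intercepts and
#' random slopes (falling back to intercepts only if the random-slope fit is
#' singular). A fixed slope above zero indicates above-chance temporal memory
#' at the group level.
#'
#' @param scored data frame with `est_rank`, `act_rank`, `participant_id`
#'   (>= 2 participants, >= 10 images each).
#' @return A `reinstatr_fit` (see [fit_mixed_linear()]) for the slope.
#' @export
fit_accuracy_model <- function(scored) {
  stopifnot(is.data.frame(scored))
  n_by <- table(scored$participant_id)
  abort_if(length(n_by) < 2L, "need at least 2 participants")
  abort_if(any(n_by < 10L), "need at least 10 images per participant")
  dat <- data.frame(est_rank = scored$est_rank, act_rank = scored$act_rank,
                    participant_id = factor(scored$participant_id))
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(est_rank ~ act_rank + (1 + act_rank | participant_id),
               data = dat, REML = FALSE)))
  if (lme4::isSingular(fit)) {
    warning("random-slope fit singular; falling back to random intercepts")
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(est_rank ~ act_rank + (1 | participant_id),
                 data = dat, REML = FALSE)))
  }
  summarize_merfit(fit, response = "est_rank", family = "gaussian")
}

#' Score final-test behavior into the per-image analysis table
#'
#' For each participant: restricts to the analysis image set (old images
#' answered correctly at all three exposures by default, mirroring typical
#' selection criteria), rank-transforms estimated and actual temporal
#' positions, computes temporal error and the precision median split, and
#' attaches log-lags.
#'
#' @param final_test final-test table.
#' @param events event table.
#' @param final_test_gap_s seconds between each participant's last trial and
#'   the final test (default 2 simulated days).
#' @param floor_seconds interval floor for lags.
#' @param require_all_correct restrict to images with CR at E1 and hits at
#'   E2/E3 (default `TRUE`).
#' @return Tibble with one row per analysis image: ranks, `temporal_error`,
#'   `precision_label` and `precision` (1 = high), `confidence`, lags.
#' @export
score_behavior <- function(final_test, events, final_test_gap_s = 172800,
                           floor_seconds = 1, require_all_correct = TRUE) {
  old <- final_test[final_test$item_type == "old", , drop = FALSE]
  if (require_all_correct) {
    keep <- old$cr_e1 & old$hit_e2 & old$hit_e3
    old <- old[!is.na(keep) & keep, , drop = FALSE]
  }
  fin_onset <- tapply(events$onset, events$participant_id, max) +
    final_test_gap_s
  lags <- compute_lags(events, fin_onset, image_id = unique(old$image_id),
                       floor_seconds = floor_seconds)
  out <- lapply(split(old, old$participant_id), function(d) {
    est_rank <- rank_transform(d$timeline_estimate)
    act_rank <- rank_transform(d$actual_E1_onset)
    err <- temporal_error(est_rank, act_rank)
    lab <- label_precision(err)
    tibble::tibble(participant_id = d$participant_id,
                   image_id = d$image_id,
                   confidence = d$confidence,
                   est_rank = est_rank, act_rank = act_rank,
                   temporal_error = err, precision_label = lab,
                   precision = as.integer(lab == "high"))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  merge_tibble(out, lags, by = c("participant_id", "image_id"))
}

# merge() preserving tibble class and row order of x
merge_tibble <- function(x, y, by) {
  x$.ord <- seq_len(nrow(x))
  m <- merge(as.data.frame(x), as.data.frame(y), by = by, all.x = TRUE,
             sort = FALSE)
  m <- m[order(m$.ord), , drop = FALSE]
  m$.ord <- NULL
  rownames(m) <- NULL
  tibble::as_tibble(m)
}
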