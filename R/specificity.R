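# Per-participant arrays used by the image-specificity analyses: E1/E2
# pattern matrices (images x voxels), run keys and onsets, aligned to the
# analysis image set.
specificity_arrays <- function(events, store, roi, images_by_participant) {
  out <- list()
  for (pid in names(images_by_participant)) {
    ids <- images_by_participant[[pid]]
    if (length(ids) == 0L) next
    ev <- store$index[[pid]]
    mat <- store$patterns[[pid]][[roi]]
    pick <- function(exposure) {
      sub <- ev[ev$image_id %in% ids & ev$exposure == exposure, , drop = FALSE]
      sub <- sub[match(ids, sub$image_id), , drop = FALSE]
      abort_if(anyNA(sub$row),
               sprintf("missing exposure %d trial for image(s) %s (%s)",
                       exposure,
                       paste(ids[is.na(sub$row)], collapse = ", "), pid))
      sub
    }
    e1 <- pick(1L)
    e2 <- pick(2L)
    out[[pid]] <- list(
      images = ids,
      e1_mat = mat[e1$row, , drop = FALSE],
      e2_mat = mat[e2$row, , drop = FALSE],
      e1_key = run_key(e1$session, e1$run),
      e2_key = run_key(e2$session, e2$run),
      e1_onset = e1$onset, e2_onset = e2$onset)
  }
  out
}

# Draw a within-participant permutation of 1..n with no fixed points
# (self-pairings rejected by full redraw).
sample_no_fixpoint <- function(n) {
  repeat {
    perm <- sample.int(n)
    if (!any(perm == seq_len(n))) return(perm)
  }
}

#' Shuffled E1-E2 mapping null for image-specific similarity effects
#'
#' Tests whether the similarity-to-precision relationship depends on the
#' image-specific E1-E2 pairing. Each permutation re-pairs every image's E1
#' with a different image's E2 within participant, recomputes the Fisher-z
#' E1-E2 similarity and the corresponding log lag1 (same-run shuffled pairs
#' are excluded, exactly as in the intact analysis), and refits the logistic
#' mixed model `precision ~ z12 + lag0 + lag1 + lag2 + lag3` with a
#' participant random intercept, collecting the similarity coefficient. The
#' observed statistic is the same coefficient under the intact mapping; p is
#' the proportion of null coefficients at or above it. Observed and null fits
#' use the identical estimator (nAGQ = 0).
#'
#' @param scored scored behavior table (with `precision` and lags), from
#'   [score_behavior()].
#' @param events event table.
#' @param store a `pattern_store`.
#' @param roi ROI name.
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @param floor_seconds interval floor before the log for recomputed lags.
#' @return A `reinstatr_perm` whose statistic is the similarity beta.
#' @export
shuffled_mapping_null <- function(scored, events, store, roi,
                                  n_perm = 1000L, seed = 1L,
                                  floor_seconds = 1) {
  stopifnot(inherits(store, "pattern_store"))
  n_by <- table(scored$participant_id)
  abort_if(any(n_by < 20L),
           "need at least 20 tested images per participant")
  images_by <- lapply(split(scored$image_id, scored$participant_id), identity)
  arr <- specificity_arrays(events, store, roi, images_by)
  # align scored rows with the concatenated per-participant image order
  sc_key <- paste(scored$participant_id, scored$image_id)
  arr_key <- unlist(lapply(names(arr), function(p)
    paste(p, arr[[p]]$images)), use.names = FALSE)
  sc <- scored[match(arr_key, sc_key), , drop = FALSE]

  flog <- function(x) log(pmax(abs(x), floor_seconds))
  intact <- lapply(arr, function(a) {
    r <- row_correlations(a$e1_mat, a$e2_mat)
    list(z = atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)),
         valid = a$e1_key != a$e2_key,
         lag1 = flog(a$e2_onset - a$e1_onset))
  })
  tab <- data.frame(
    precision = sc$precision,
    z12 = unlist(lapply(intact, `[[`, "z"), use.names = FALSE),
    lag0 = sc$lag0,
    lag1 = unlist(lapply(intact, `[[`, "lag1"), use.names = FALSE),
    lag2 = sc$lag2, lag3 = sc$lag3,
    participant_id = sc$participant_id)
  fixed <- c("z12", "lag0", "lag1", "lag2", "lag3")
  rf <- make_perm_refitter(tab, "precision", fixed, "participant_id")
  w_intact <- as.numeric(unlist(lapply(intact, `[[`, "valid"),
                                use.names = FALSE))
  observed <- perm_refit(rf, columns = list(z12 = tab$z12, lag1 = tab$lag1),
                         weights = w_intact)[["z12"]]
  null_values <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      z <- numeric(0); l1 <- numeric(0); w <- numeric(0)
      for (a in arr) {
        n <- length(a$images)
        perm <- sample_no_fixpoint(n)
        r <- row_correlations(a$e1_mat, a$e2_mat[perm, , drop = FALSE])
        z <- c(z, atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)))
        l1 <- c(l1, flog(a$e2_onset[perm] - a$e1_onset))
        w <- c(w, as.numeric(a$e1_key != a$e2_key[perm]))
      }
      perm_refit(rf, columns = list(z12 = z, lag1 = l1),
                 weights = w)[["z12"]]
    }, numeric(1))
  })
  new_permutation_result(observed, null_values, direction = "ge",
                         n_perm = n_perm, seed = seed)
}

#' Find session-matched behavioral foils for a target image
#'
#' A foil shares the target's E1 session and E2 session but occurred in a
#' different run at both exposures, and received the same continuous-
#' recognition judgments as analysis targets: correct rejection at E1 and
#' hits at E2 and E3. An empty foil list is a valid outcome.
#'
#' @param target target image id.
#' @param image_summary per-image table for one participant with columns
#'   `image_id`, `e1_session`, `e1_run`, `e2_session`, `e2_run`, `cr_e1`,
#'   `hit_e2`, `hit_e3`.
#' @return Character vector of foil image ids (deterministic, order of
#'   appearance in `image_summary`).
#' @export
find_foils <- function(target, image_summary) {
  stopifnot(is.data.frame(image_summary))
  tg <- image_summary[image_summary$image_id == target, , drop = FALSE]
  abort_if(nrow(tg) != 1L, sprintf("target %s not found exactly once", target))
  cand <- image_summary[image_summary$image_id != target, , drop = FALSE]
  ok <- cand$e1_session == tg$e1_session & cand$e1_run != tg$e1_run &
    cand$e2_session == tg$e2_session & cand$e2_run != tg$e2_run &
    cand$cr_e1 & cand$hit_e2 & cand$hit_e3
  cand$image_id[!is.na(ok) & ok]
}

# Build the per-image summary (exposure sessions/runs + correctness flags)
# for one participant from the event table and final-test outcomes.
image_summary_for <- function(events, final_test, pid) {
  ev <- events[events$participant_id == pid & !events$is_filler, ,
               drop = FALSE]
  wide <- lapply(split(ev, ev$image_id), function(d) {
    d <- d[order(d$exposure), , drop = FALSE]
    tibble::tibble(image_id = d$image_id[1L],
                   e1_session = d$session[1L], e1_run = d$run[1L],
                   e2_session = d$session[2L], e2_run = d$run[2L],
                   e3_session = d$session[3L], e3_run = d$run[3L])
  })
  wide <- do.call(rbind, wide)
  ft <- final_test[final_test$participant_id == pid &
                     final_test$item_type == "old",
                   c("image_id", "cr_e1", "hit_e2", "hit_e3"), drop = FALSE]
  merge_tibble(wide, ft, by = "image_id")
}

#' Target-versus-foil image-specific similarity scores
#'
#' For each target: target similarity is the Fisher z of r(target E1, target
#' E2); foil similarity is the Fisher z of r(target E1, foil E2), taking the
#' median over foils when two or more exist. The difference (target - foil)
#' indexes image-specific pattern similarity purged of session-level and
#' generic memory effects. Targets with no foils are excluded; their count is
#' reported in the `n_excluded` attribute.
#'
#' @param events event table.
#' @param final_test final-test table (for foil behavioral criteria).
#' @param store a `pattern_store`.
#' @param roi ROI name.
#' @param targets data frame with `participant_id`, `image_id` naming the
#'   target images (typically the scored analysis set).
#' @return Tibble with `participant_id`, `target_image_id`, `n_foils`,
#'   `target_similarity`, `foil_similarity`, `difference`.
#' @export
specificity_scores <- function(events, final_test, store, roi, targets) {
  out <- list()
  n_excluded <- 0L
  for (pid in unique(targets$participant_id)) {
    summ <- image_summary_for(events, final_test, pid)
    ids <- targets$image_id[targets$participant_id == pid]
    ev <- store$index[[pid]]
    mat <- store$patterns[[pid]][[roi]]
    row_of <- function(img, exposure) {
      r <- ev$row[ev$image_id == img & ev$exposure == exposure]
      abort_if(length(r) != 1L,
               sprintf("missing pattern row for image %s exposure %d (%s)",
                       img, exposure, pid))
      r
    }
    rows <- lapply(ids, function(img) {
      foils <- find_foils(img, summ)
      if (length(foils) == 0L) {
        n_excluded <<- n_excluded + 1L
        return(NULL)
      }
      e1 <- mat[row_of(img, 1L), ]
      tz <- fisher_z(pattern_correlation(e1, mat[row_of(img, 2L), ]))
      fz <- vapply(foils, function(f)
        fisher_z(pattern_correlation(e1, mat[row_of(f, 2L), ])), numeric(1))
      tibble::tibble(participant_id = pid, target_image_id = img,
                     n_foils = length(foils), target_similarity = tz,
                     foil_similarity = median(fz),
                     difference = tz - median(fz))
    })
    out[[pid]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- tibble::tibble(participant_id = character(),
                          target_image_id = character(),
                          n_foils = integer(), target_similarity = numeric(),
                          foil_similarity = numeric(), difference = numeric())
  }
  rownames(res) <- NULL
  attr(res, "n_excluded") <- n_excluded
  res
}

#' Logistic mixed model of precision on the target-foil difference score
#'
#' Convenience wrapper: joins specificity scores to the scored behavior table
#' and fits `precision ~ difference + lag0 + lag1 + lag2 + lag3` with a
#' participant random intercept.
#'
#' @param spec_table output of [specificity_scores()].
#' @param scored scored behavior table.
#' @return A `reinstatr_fit`.
#' @export
fit_specificity_model <- function(spec_table, scored) {
  d <- merge(as.data.frame(spec_table), as.data.frame(scored),
             by.x = c("participant_id", "target_image_id"),
             by.y = c("participant_id", "image_id"))
  fit_mixed_logistic(d, "precision",
                     c("difference", "lag0", "lag1", "lag2", "lag3"))
}
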