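#' Pearson correlation between two voxel patterns
#'
#' @param a,b equal-length numeric vectors (length >= 2) with nonzero
#'   variance. A zero-variance pattern is an error, never silently 0.
#' @return Correlation in `[-1, 1]`.
#' @export
pattern_correlation <- function(a, b) {
  abort_if(length(a) != length(b), "patterns must have equal length")
  abort_if(length(a) < 2L, "patterns must have length >= 2")
  abort_if(!all(is.finite(a)) || !all(is.finite(b)),
           "patterns must be finite")
  abort_if(sd(a) == 0 || sd(b) == 0,
           "undefined correlation: a pattern has zero variance")
  cor(a, b)
}

#' Fisher z-transform of a correlation coefficient
#'
#' The variance-stabilizing transform `z = atanh(r)`; odd and strictly
#' increasing on (-1, 1).
#'
#' @param r correlation(s) with `|r| < 1`.
#' @return Fisher z value(s).
#' @export
fisher_z <- function(r) {
  abort_if(any(!is.finite(r)) || any(abs(r) >= 1),
           "fisher_z requires |r| < 1")
  atanh(r)
}

# Run identity: session and run jointly identify a scanning run.
run_key <- function(session, run) paste0(session, "_", run)

#' Exposure-pair pattern similarities with cross-run exclusion
#'
#' For each image with three exposures, correlates the stored voxel patterns
#' of every exposure pair (E1-E2, E2-E3, E1-E3) within one ROI. A pair is
#' valid only if its two exposures occurred in different scanning runs
#' (session and run jointly identify a run); same-run pairs are excluded to
#' avoid scanner-induced autocorrelation inflating similarity. Valid
#' correlations are Fisher-transformed and averaged into `mean_z`.
#'
#' @param events event table.
#' @param store a `pattern_store`.
#' @param roi ROI name.
#' @param images optional subset of image ids (default: all non-filler).
#' @return Tibble with one row per participant x image: `r12`, `r23`, `r13`,
#'   `z12`, `z23`, `z13` (NA when invalid), validity flags, `n_valid` and
#'   `mean_z` (NA when no valid pair).
#' @export
exposure_similarities <- function(events, store, roi, images = NULL) {
  stopifnot(inherits(store, "pattern_store"))
  abort_if(!(roi %in% store$roi_names),
           sprintf("ROI %s not present in pattern store", roi))
  out <- list()
  for (pid in names(store$index)) {
    ev <- store$index[[pid]]
    mat <- store$patterns[[pid]][[roi]]
    ids <- unique(ev$image_id[!ev$is_filler])
    if (!is.null(images)) ids <- intersect(ids, images)
    if (length(ids) == 0L) next
    ids <- sort(ids)
    rows_of <- function(exposure) {
      sub <- ev[ev$image_id %in% ids & ev$exposure == exposure, , drop = FALSE]
      r <- sub$row[match(ids, sub$image_id)]
      abort_if(anyNA(r),
               sprintf("image(s) %s lack stored patterns for exposure %d (%s)",
                       paste(ids[is.na(r)], collapse = ", "), exposure, pid))
      abort_if(any(r > nrow(mat)),
               sprintf("missing pattern rows for participant %s", pid))
      r
    }
    rows <- lapply(1:3, rows_of)
    sub_mat <- mat[unlist(rows), , drop = FALSE]
    sds <- rowSums((sub_mat - rowMeans(sub_mat))^2)
    abort_if(any(sds == 0),
             sprintf("undefined correlation: zero-variance pattern (%s)", pid))
    keys <- lapply(rows, function(r) run_key(ev$session[r], ev$run[r]))
    pair_idx <- list(c(1L, 2L), c(2L, 3L), c(1L, 3L))
    r_mat <- vapply(pair_idx, function(p)
      row_correlations(mat[rows[[p[1L]]], , drop = FALSE],
                       mat[rows[[p[2L]]], , drop = FALSE]),
      numeric(length(ids)))
    valid_mat <- vapply(pair_idx, function(p)
      keys[[p[1L]]] != keys[[p[2L]]], logical(length(ids)))
    r_mat <- matrix(r_mat, ncol = 3L)
    valid_mat <- matrix(valid_mat, ncol = 3L)
    z_mat <- atanh(pmin(pmax(r_mat, -1 + 1e-15), 1 - 1e-15))
    z_mat[!valid_mat] <- NA_real_
    r_mat[!valid_mat] <- NA_real_
    n_valid <- rowSums(valid_mat)
    mean_z <- rowMeans(z_mat, na.rm = TRUE)
    mean_z[n_valid == 0L] <- NA_real_
    out[[pid]] <- tibble::tibble(
      participant_id = pid, image_id = ids, roi = roi,
      r12 = r_mat[, 1L], r23 = r_mat[, 2L], r13 = r_mat[, 3L],
      z12 = z_mat[, 1L], z23 = z_mat[, 2L], z13 = z_mat[, 3L],
      valid12 = valid_mat[, 1L], valid23 = valid_mat[, 2L],
      valid13 = valid_mat[, 3L],
      n_valid = n_valid, mean_z = mean_z)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' High- vs low-precision similarity permutation test
#'
#' The group statistic is the across-participant mean of the within-
#' participant difference in mean similarity between high- and low-precision
#' images. The null shuffles the images' precision labels within each
#' participant and recomputes the statistic; p is the proportion of null
#' values at or above the observed one (one-sided: high > low).
#'
#' @param sim_table output of [exposure_similarities()].
#' @param labels data frame with `participant_id`, `image_id` and
#'   `precision_label` (`"high"`/`"low"`).
#' @param pair which similarity to test: `"mean"` (mean_z) or one of
#'   `"z12"`, `"z23"`, `"z13"`.
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @return A `reinstatr_perm` object.
#' @export
high_low_permutation <- function(sim_table, labels,
                                 pair = c("mean", "z12", "z23", "z13"),
                                 n_perm = 1000L, seed = 1L) {
  pair <- match.arg(pair)
  col <- if (pair == "mean") "mean_z" else pair
  d <- merge_tibble(sim_table, labels[, c("participant_id", "image_id",
                                          "precision_label")],
                    by = c("participant_id", "image_id"))
  d <- d[!is.na(d[[col]]) & !is.na(d$precision_label), , drop = FALSE]
  by_p <- split(d, d$participant_id)
  by_p <- Filter(function(x) {
    ok <- all(c("high", "low") %in% x$precision_label)
    if (!ok) warning(sprintf(
      "participant %s lacks one label class; dropped", x$participant_id[1L]))
    ok
  }, by_p)
  abort_if(length(by_p) < 2L,
           "need >= 2 participants with both precision labels")
  obs_diff <- function(z, is_high) mean(z[is_high]) - mean(z[!is_high])
  zs <- lapply(by_p, function(x) x[[col]])
  highs <- lapply(by_p, function(x) x$precision_label == "high")
  observed <- mean(mapply(obs_diff, zs, highs))
  null_values <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      mean(mapply(function(z, h) obs_diff(z, sample(h)), zs, highs))
    }, numeric(1))
  })
  new_permutation_result(observed, null_values, direction = "ge",
                         n_perm = n_perm, seed = seed)
}
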