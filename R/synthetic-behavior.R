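#' Generate final-memory-test behavior from the planted latents
#'
#' The timeline estimate for image i is the true normalized first-exposure
#' position plus Gaussian noise with sd `sigma0 * exp(-kappa_precision *
#' rho_i)`, truncated to `[0, 1]` (the physical timeline). Recognition
#' confidence is a fixed monotone discretization of `kappa_confidence *
#' (m_i - 1/2) + bias + noise` onto 1-6; novel images use a lower bias and no
#' latent. Continuous-recognition correctness flags (correct rejection at E1,
#' hits at E2/E3) are sampled at the configured rates so that downstream foil
#' pools are non-trivial.
#'
#' @param design event table from [generate_design()].
#' @param truth `ground_truth` from [generate_patterns()].
#' @param seed integer seed.
#' @param n_novel novel (never-presented) images per participant added to the
#'   final test for false-alarm estimation.
#' @return A tibble (final-test table) with one row per tested image:
#'   `participant_id`, `image_id`, `item_type` ("old"/"novel"), `confidence`
#'   (1-6), `frequency_response` (1-4, old only), `timeline_estimate` (fraction
#'   of timeline, old only), `actual_E1_onset` (seconds), and correctness flags
#'   `cr_e1`, `hit_e2`, `hit_e3` (old only).
#' @export
generate_behavior <- function(design, truth, seed = 1L, n_novel = 50L) {
  stopifnot(is.data.frame(design), inherits(truth, "ground_truth"))
  tp <- truth$truth_params
  participants <- unique(design$participant_id)
  conf_breaks <- c(-Inf, -0.9, -0.45, 0, 0.45, 0.9, Inf)
  rows <- list()
  with_seed(seed, {
    for (pid in participants) {
      ev <- design[design$participant_id == pid & !design$is_filler, ,
                   drop = FALSE]
      by_img <- split(ev, ev$image_id)
      n_exp <- vapply(by_img, nrow, integer(1))
      abort_if(any(n_exp != 3L),
               sprintf("image(s) %s lack 3 exposures for participant %s",
                       paste(names(by_img)[n_exp != 3L], collapse = ", "),
                       pid))
      ids <- names(by_img)
      e1_onset <- vapply(by_img, function(d) d$onset[d$exposure == 1L],
                         numeric(1))
      lat <- truth$image[truth$image$participant_id == pid, , drop = FALSE]
      rho <- setNames(lat$rho, lat$image_id)[ids]
      m <- setNames(lat$m, lat$image_id)[ids]
      total <- max(design$onset[design$participant_id == pid]) +
        min(diff(sort(unique(design$onset[design$participant_id == pid]))))
      true_pos <- e1_onset / total
      est_sd <- tp$sigma0 * exp(-tp$kappa_precision * rho)
      est <- pmin(pmax(true_pos + rnorm(length(ids)) * est_sd, 0), 1)
      conf_lat <- tp$kappa_confidence * (m - 0.5) + tp$conf_bias_old +
        rnorm(length(ids), sd = tp$conf_noise_sd)
      confidence <- as.integer(cut(conf_lat, conf_breaks))
      freq <- pmin(pmax(as.integer(round(3 + rnorm(length(ids), sd = 0.7))),
                        1L), 4L)
      old <- tibble::tibble(
        participant_id = pid, image_id = ids, item_type = "old",
        confidence = confidence, frequency_response = freq,
        timeline_estimate = unname(est), actual_E1_onset = unname(e1_onset),
        cr_e1 = runif(length(ids)) < tp$p_cr_e1,
        hit_e2 = runif(length(ids)) < tp$p_hit_e2,
        hit_e3 = runif(length(ids)) < tp$p_hit_e3)
      conf_new <- as.integer(cut(tp$conf_bias_new +
                                   rnorm(n_novel, sd = tp$conf_noise_sd),
                                 conf_breaks))
      novel <- tibble::tibble(
        participant_id = pid, image_id = sprintf("nov%04d", seq_len(n_novel)),
        item_type = "novel", confidence = conf_new,
        frequency_response = NA_integer_, timeline_estimate = NA_real_,
        actual_E1_onset = NA_real_, cr_e1 = NA, hit_e2 = NA, hit_e3 = NA)
      rows[[pid]] <- rbind(old, novel)
    }
  })
  do.call(rbind, rows)
}

#' Simulate a full synthetic experiment
#'
#' Convenience wrapper chaining [generate_design()], [generate_patterns()] and
#' [generate_behavior()] with seeds derived from one master seed.
#'
#' @param params [design_params()]; its `seed` is overridden by `seed`.
#' @param rois list of [roi_spec()].
#' @param truth [truth_params()].
#' @param seed master integer seed.
#' @param n_novel novel images per participant in the final test.
#' @return List with `events`, `store`, `truth`, `final_test`.
#' @export
simulate_experiment <- function(params = design_params(),
                                rois = default_rois(),
                                truth = truth_params(),
                                seed = 1L, n_novel = 50L) {
  params$seed <- derive_seed(seed, 1L)
  events <- generate_design(params)
  pat <- generate_patterns(events, rois, truth, seed = derive_seed(seed, 2L))
  final_test <- generate_behavior(events, pat$truth,
                                  seed = derive_seed(seed, 3L),
                                  n_novel = n_novel)
  list(events = events, store = pat$store, truth = pat$truth,
       final_test = final_test)
}

#' Default ROI set for simulation
#'
#' One medial-temporal region carrying the precision coupling (labelled CA1),
#' one region carrying the confidence coupling (labelled PHC), and one control
#' region with no reinstatement (labelled V1).
#'
#' @param n_voxels voxels per region.
#' @return List of [roi_spec()].
#' @export
default_rois <- function(n_voxels = 100) {
  list(
    roi_spec("CA1", n_voxels = n_voxels, role = "precision"),
    roi_spec("PHC", n_voxels = n_voxels, role = "confidence"),
    roi_spec("V1", n_voxels = n_voxels, role = "none")
  )
}
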