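#' ROI specification for the synthetic pattern generator
#'
#' Each region of interest carries three signal components per voxel: a fixed
#' image-specific vector, a temporal-context signal, and i.i.d. noise. The
#' context signal is the sum of a shared per-session component and a
#' trial-level first-order autoregressive (Ornstein-Uhlenbeck-type) drift with
#' timescale `tau` measured in trials. The `role` field states which latent
#' couples to reinstatement in this region:
#'
#' * `"precision"`: at exposures 2 and 3 of image i the context component is
#'   `rho_i * c_E1 + sqrt(1 - rho_i^2) * c_t`, re-expressing the trial-specific
#'   context of the first exposure with the image's reinstatement strength.
#' * `"confidence"`: the same mixing, but at exposure 3 only and with the
#'   image's memory-strength latent `m_i` as the weight.
#' * `"session"`: repeats re-express the shared session component of the first
#'   exposure's session with a constant weight -- coarse temporal context with
#'   no image-specific information.
#' * `"none"`: no reinstatement.
#'
#' @param roi_name label, e.g. `"CA1"`.
#' @param n_voxels voxels in the region (>= 2).
#' @param tau context drift timescale in trials (> 0).
#' @param image_signal_sd,context_signal_sd,session_signal_sd,noise_sd
#'   amplitude (percent-signal-change-like) standard deviations, all >= 0.
#' @param role one of `"precision"`, `"confidence"`, `"session"`, `"none"`.
#' @param session_reinstate_weight constant mixing weight used when
#'   `role = "session"`.
#' @param reinstate_at exposure indices at which reinstatement happens;
#'   `NULL` uses the role's default (2 and 3 for precision/session, 3 for
#'   confidence).
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(roi_name, n_voxels = 100, tau = 30,
                     image_signal_sd = 1, context_signal_sd = 1,
                     session_signal_sd = 0.5, noise_sd = 1,
                     role = c("none", "precision", "confidence", "session"),
                     session_reinstate_weight = 0.5,
                     reinstate_at = NULL) {
  role <- match.arg(role)
  abort_if(!is.null(reinstate_at) && !all(reinstate_at %in% 2:3),
           "reinstate_at must be a subset of c(2, 3)")
  abort_if(n_voxels < 2, "n_voxels must be >= 2")
  abort_if(tau <= 0, "tau must be positive")
  sds <- c(image_signal_sd, context_signal_sd, session_signal_sd, noise_sd)
  abort_if(any(sds < 0), "signal/noise standard deviations must be >= 0")
  abort_if(session_reinstate_weight < 0 || session_reinstate_weight > 1,
           "session_reinstate_weight must lie in [0, 1]")
  structure(list(roi_name = roi_name, n_voxels = as.integer(n_voxels),
                 tau = tau, image_signal_sd = image_signal_sd,
                 context_signal_sd = context_signal_sd,
                 session_signal_sd = session_signal_sd, noise_sd = noise_sd,
                 role = role,
                 session_reinstate_weight = session_reinstate_weight,
                 reinstate_at = reinstate_at),
            class = "roi_spec")
}

#' Ground-truth (latent) parameters for the generator
#'
#' @param rho_shape1,rho_shape2 Beta parameters for the per-image reinstatement
#'   strength `rho_i` (default Beta(2, 2): bounded, symmetric, with spread).
#' @param rho_fixed if non-`NULL`, a constant in `[0, 1]` used for every
#'   image's `rho_i` instead of the Beta draw (zero reinstatement variance).
#' @param m_shape1,m_shape2 Beta parameters for the per-image memory strength
#'   `m_i`, drawn independently of `rho_i`.
#' @param kappa_precision coupling of `rho_i` to timeline-estimate noise: the
#'   estimate's Gaussian sd is `sigma0 * exp(-kappa_precision * rho_i)`.
#' @param kappa_confidence coupling of `m_i` to the latent driving the 1-6
#'   recognition-confidence rating.
#' @param sigma0 baseline timeline-estimate sd (fraction of the timeline).
#' @param conf_bias_old,conf_bias_new location of the confidence latent for
#'   old/novel images (old-biased positive so hit rates are realistic).
#' @param conf_noise_sd sd of the confidence latent noise.
#' @param p_cr_e1,p_hit_e2,p_hit_e3 continuous-recognition correctness rates
#'   (correct rejection at first exposure, hits at repeats).
#' @param session_gap_drift extra drift time (in trials) inserted between
#'   consecutive sessions; `NULL` means one session's worth of trials.
#' @return An object of class `truth_params`.
#' @export
truth_params <- function(rho_shape1 = 2, rho_shape2 = 2, rho_fixed = NULL,
                         m_shape1 = 2, m_shape2 = 2,
                         kappa_precision = 2, kappa_confidence = 2,
                         sigma0 = 0.25,
                         conf_bias_old = 0.6, conf_bias_new = -0.55,
                         conf_noise_sd = 0.55,
                         p_cr_e1 = 0.9, p_hit_e2 = 0.92, p_hit_e3 = 0.94,
                         session_gap_drift = NULL) {
  abort_if(sigma0 < 0, "sigma0 must be >= 0")
  abort_if(any(c(rho_shape1, rho_shape2, m_shape1, m_shape2) <= 0),
           "Beta shape parameters must be positive")
  abort_if(!is.finite(kappa_precision) || !is.finite(kappa_confidence),
           "coupling coefficients must be finite")
  rates <- c(p_cr_e1, p_hit_e2, p_hit_e3)
  abort_if(any(rates < 0 | rates > 1), "correctness rates must lie in [0, 1]")
  abort_if(!is.null(rho_fixed) && (rho_fixed < 0 || rho_fixed > 1),
           "rho_fixed must lie in [0, 1]")
  structure(list(rho_shape1 = rho_shape1, rho_shape2 = rho_shape2,
                 rho_fixed = rho_fixed,
                 m_shape1 = m_shape1, m_shape2 = m_shape2,
                 kappa_precision = kappa_precision,
                 kappa_confidence = kappa_confidence, sigma0 = sigma0,
                 conf_bias_old = conf_bias_old, conf_bias_new = conf_bias_new,
                 conf_noise_sd = conf_noise_sd,
                 p_cr_e1 = p_cr_e1, p_hit_e2 = p_hit_e2, p_hit_e3 = p_hit_e3,
                 session_gap_drift = session_gap_drift),
            class = "truth_params")
}

# Simulate a stationary OU chain (n x V) at drift times u with timescale tau.
simulate_ou <- function(u, n_voxels, sd, tau) {
  n <- length(u)
  c_mat <- matrix(0, n, n_voxels)
  if (sd == 0 || n == 0L) return(c_mat)
  c_mat[1L, ] <- rnorm(n_voxels, sd = sd)
  if (n > 1L) {
    phi <- exp(-diff(u) / tau)
    innov_sd <- sd * sqrt(1 - phi^2)
    for (t in 2L:n) {
      c_mat[t, ] <- phi[t - 1L] * c_mat[t - 1L, ] +
        rnorm(n_voxels, sd = innov_sd[t - 1L])
    }
  }
  c_mat
}

#' Generate synthetic trial-level activity patterns with planted reinstatement
#'
#' Per trial the pattern is `x_t = s_img(i) + context_t + eps_t`: a fixed
#' image-specific vector, a drifting temporal-context signal (shared session
#' component plus OU trial drift), and i.i.d. Gaussian noise. At repeat
#' exposures the context component mixes in the first exposure's context
#' according to the region's role (see [roi_spec()]), which plants the
#' image-specific reinstatement structure the downstream analyses are designed
#' to detect.
#'
#' @param design event table from [generate_design()].
#' @param rois list of [roi_spec()] objects.
#' @param truth a [truth_params()] object.
#' @param seed integer seed.
#' @return A list with `store` (a `pattern_store`: per-participant, per-ROI
#'   trial-by-voxel matrices aligned to the event-table rows) and `truth` (a
#'   `ground_truth` list recording every latent: per-image `rho` and `m`,
#'   coupling coefficients, and the ROI role map).
#' @export
generate_patterns <- function(design, rois, truth = truth_params(),
                              seed = 1L) {
  stopifnot(is.data.frame(design), inherits(truth, "truth_params"))
  abort_if(length(rois) == 0L, "rois must be a non-empty list of roi_spec")
  if (inherits(rois, "roi_spec")) rois <- list(rois)
  for (r in rois) stopifnot(inherits(r, "roi_spec"))
  roi_names <- vapply(rois, `[[`, character(1), "roi_name")
  abort_if(anyDuplicated(roi_names) > 0L, "roi names must be unique")

  participants <- unique(design$participant_id)
  patterns <- list()
  index <- list()
  truth_rows <- list()
  with_seed(seed, {
    for (pid in participants) {
      ev <- design[design$participant_id == pid, , drop = FALSE]
      ev <- ev[order(ev$onset), , drop = FALSE]
      ev$row <- seq_len(nrow(ev))
      index[[pid]] <- ev
      old_ids <- sort(unique(ev$image_id[!ev$is_filler]))
      rho <- if (!is.null(truth$rho_fixed)) {
        rep(truth$rho_fixed, length(old_ids))
      } else {
        rbeta(length(old_ids), truth$rho_shape1, truth$rho_shape2)
      }
      m <- rbeta(length(old_ids), truth$m_shape1, truth$m_shape2)
      names(rho) <- names(m) <- old_ids
      truth_rows[[pid]] <- tibble::tibble(participant_id = pid,
                                          image_id = old_ids,
                                          rho = unname(rho), m = unname(m))
      trials_per_session <- tabulate(ev$session)
      gap <- truth$session_gap_drift
      if (is.null(gap)) gap <- max(trials_per_session)
      u <- seq_len(nrow(ev)) + (ev$session - 1L) * gap
      patterns[[pid]] <- list()
      for (r in rois) {
        patterns[[pid]][[r$roi_name]] <-
          generate_roi_patterns(ev, r, rho, m, u)
      }
    }
  })
  store <- structure(list(patterns = patterns, index = index,
                          roi_names = roi_names),
                     class = "pattern_store")
  gt <- structure(list(
    image = do.call(rbind, truth_rows),
    kappa_precision = truth$kappa_precision,
    kappa_confidence = truth$kappa_confidence,
    sigma0 = truth$sigma0,
    truth_params = truth,
    roi_roles = tibble::tibble(
      roi_name = roi_names,
      role = vapply(rois, `[[`, character(1), "role"))
  ), class = "ground_truth")
  list(store = store, truth = gt)
}

generate_roi_patterns <- function(ev, roi, rho, m, u) {
  n <- nrow(ev)
  V <- roi$n_voxels
  image_ids <- unique(ev$image_id)
  s_img <- matrix(rnorm(length(image_ids) * V, sd = roi$image_signal_sd),
                  nrow = length(image_ids), dimnames = list(image_ids, NULL))
  sessions <- sort(unique(ev$session))
  b_sess <- matrix(rnorm(length(sessions) * V, sd = roi$session_signal_sd),
                   nrow = length(sessions),
                   dimnames = list(as.character(sessions), NULL))
  ou <- simulate_ou(u, V, roi$context_signal_sd, roi$tau)
  ctx <- b_sess[as.character(ev$session), , drop = FALSE] + ou

  # reinstatement: mix the E1 reference into the repeat's ambient context
  used_ctx <- ctx
  if (roi$role != "none") {
    e1_row_of <- tapply(seq_len(n)[ev$exposure == 1L],
                        ev$image_id[ev$exposure == 1L], identity)
    reinstate_at <- roi$reinstate_at
    if (is.null(reinstate_at)) {
      reinstate_at <- switch(roi$role,
                             precision = c(2L, 3L),
                             confidence = 3L,
                             session = c(2L, 3L))
    }
    for (t in which(ev$exposure %in% reinstate_at & !ev$is_filler)) {
      img <- ev$image_id[t]
      w <- switch(roi$role,
                  precision = rho[[img]],
                  confidence = m[[img]],
                  session = roi$session_reinstate_weight)
      e1 <- e1_row_of[[img]]
      ref <- if (roi$role == "session") {
        b_sess[as.character(ev$session[e1]), ]
      } else {
        ctx[e1, ]
      }
      used_ctx[t, ] <- w * ref + sqrt(1 - w^2) * ctx[t, ]
    }
  }
  noise <- matrix(rnorm(n * V, sd = roi$noise_sd), n, V)
  s_img[ev$image_id, , drop = FALSE] + used_ctx + noise
}

#' Retrieve the pattern vector for one trial
#'
#' @param store a `pattern_store`.
#' @param participant_id,roi_name identifiers.
#' @param row event-table row index (chronological within participant).
#' @return Numeric voxel vector.
#' @export
get_pattern <- function(store, participant_id, roi_name, row) {
  stopifnot(inherits(store, "pattern_store"))
  mat <- store$patterns[[participant_id]][[roi_name]]
  abort_if(is.null(mat),
           sprintf("no patterns stored for participant %s, ROI %s",
                   participant_id, roi_name))
  abort_if(row < 1L || row > nrow(mat),
           sprintf("no pattern row %d for participant %s (ROI %s has %d rows)",
                   row, participant_id, roi_name, nrow(mat)))
  mat[row, ]
}
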