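#' Design parameters for a synthetic continuous-recognition experiment
#'
#' Describes the temporal skeleton of the experiment: how many participants,
#' sessions, runs and trials, how many images are shown three times each, and
#' how repeats are spaced. Repeat spacing uses a two-component model: with
#' probability `p_within_session_repeat` a repeat lands in the same session as
#' the previous exposure, otherwise uniformly in a later session. Sessions are
#' separated by a fixed gap (`session_gap_s`, default one simulated day), so
#' exposure lags span seconds to weeks on the log scale.
#'
#' @param n_participants number of participants.
#' @param n_sessions scan sessions per participant.
#' @param runs_per_session runs per session.
#' @param trials_per_run trials per run.
#' @param n_images number of images presented exactly three times each; slots
#'   left over are filled with single-exposure filler images.
#' @param trial_duration_s trial duration in seconds.
#' @param p_within_session_repeat probability that a repeat occurs in the same
#'   session as the preceding exposure.
#' @param session_gap_s gap between consecutive session starts, seconds.
#' @param seed integer seed making the design deterministic.
#' @return An object of class `design_params` (a validated list).
#' @export
design_params <- function(n_participants = 8,
                          n_sessions = 10,
                          runs_per_session = 5,
                          trials_per_run = 15,
                          n_images = 150,
                          trial_duration_s = 4,
                          p_within_session_repeat = 0.3,
                          session_gap_s = 86400,
                          seed = 1L) {
  p <- list(n_participants = as.integer(n_participants),
            n_sessions = as.integer(n_sessions),
            runs_per_session = as.integer(runs_per_session),
            trials_per_run = as.integer(trials_per_run),
            n_images = as.integer(n_images),
            trial_duration_s = trial_duration_s,
            p_within_session_repeat = p_within_session_repeat,
            session_gap_s = session_gap_s,
            seed = as.integer(seed))
  counts <- c("n_participants", "n_sessions", "runs_per_session",
              "trials_per_run", "n_images")
  for (nm in counts) abort_if(p[[nm]] < 1L, paste0(nm, " must be >= 1"))
  abort_if(p$p_within_session_repeat < 0 || p$p_within_session_repeat > 1,
           "p_within_session_repeat must lie in [0, 1]")
  abort_if(p$trial_duration_s <= 0, "trial_duration_s must be positive")
  abort_if(p$session_gap_s <= 0, "session_gap_s must be positive")
  n_slots <- p$n_sessions * p$runs_per_session * p$trials_per_run
  abort_if(3L * p$n_images > n_slots,
           sprintf(paste0("infeasible packing: %d exposures (3 x %d images) ",
                          "exceed %d trial slots (n_sessions x ",
                          "runs_per_session x trials_per_run)"),
                   3L * p$n_images, p$n_images, n_slots))
  structure(p, class = "design_params")
}

# Draw the session for one exposure. `from` is the session of the previous
# exposure (NA for E1). `free` is the per-session count of unassigned slots.
# `remaining` exposures of the same image must still fit at or after the
# chosen session, so a session is eligible only if taking one of its slots
# leaves that much capacity in itself and later sessions.
draw_exposure_session <- function(from, free, p_within, remaining) {
  n_sessions <- length(free)
  tail_free <- rev(cumsum(rev(free)))          # free slots at or after s
  feasible <- free > 0L & (tail_free - 1L) >= remaining
  open <- which(feasible)
  if (is.na(from)) {
    abort_if(length(open) == 0L,
             "infeasible packing: no session can host a first exposure and its repeats")
    if (length(open) == 1L) return(open)
    return(sample(open, 1L, prob = free[open]))
  }
  later <- open[open > from]
  same_ok <- feasible[from]
  if (length(later) == 0L) {
    abort_if(!same_ok,
             sprintf(paste0("infeasible packing: exposure after session %d ",
                            "has no feasible slot in that session or later"),
                     from))
    return(from)
  }
  if (same_ok && runif(1) < p_within) return(from)
  # uniform over the free slots of later sessions (capacity-weighted
  # session choice keeps the stream from jamming its final sessions)
  if (length(later) == 1L) later else sample(later, 1L, prob = free[later])
}

#' Generate the trial-level design of a synthetic experiment
#'
#' Places three exposures of each of `n_images` images into trial slots so that
#' exposure sessions are non-decreasing and onsets strictly increase with
#' exposure index. Remaining slots become single-exposure filler images, as in
#' a continuous-recognition stream where most trials are not later probed.
#'
#' @param params a [design_params()] object.
#' @return A tibble (the event table) with one row per trial and columns
#'   `participant_id`, `session`, `run`, `trial` (1-based within run), `onset`
#'   (seconds from each participant's experiment start), `image_id`,
#'   `exposure` (1-3) and `is_filler`.
#' @export
generate_design <- function(params) {
  stopifnot(inherits(params, "design_params"))
  with_seed(params$seed, {
    out <- vector("list", params$n_participants)
    for (pp in seq_len(params$n_participants)) {
      out[[pp]] <- generate_design_one(params, pp)
    }
  })
  do.call(rbind, out)
}

generate_design_one <- function(params, participant) {
  S <- params$n_sessions
  R <- params$runs_per_session
  Tr <- params$trials_per_run
  per_session <- R * Tr
  n_slots <- S * per_session

  # session choice per exposure, capacity-aware; rare unlucky packings (a
  # late-session E1 whose forced same-session repeats no longer fit) are
  # retried a bounded number of times before raising a capacity error
  sess <- NULL
  for (attempt in seq_len(20L)) {
    res <- tryCatch({
      free <- rep(per_session, S)
      sess_try <- matrix(NA_integer_, nrow = params$n_images, ncol = 3L)
      for (i in sample(seq_len(params$n_images))) {
        s1 <- draw_exposure_session(NA, free,
                                    params$p_within_session_repeat, 2L)
        free[s1] <- free[s1] - 1L
        s2 <- draw_exposure_session(s1, free,
                                    params$p_within_session_repeat, 1L)
        free[s2] <- free[s2] - 1L
        s3 <- draw_exposure_session(s2, free,
                                    params$p_within_session_repeat, 0L)
        free[s3] <- free[s3] - 1L
        sess_try[i, ] <- c(s1, s2, s3)
      }
      sess_try
    }, error = function(e) e)
    if (!inherits(res, "error")) { sess <- res; break }
    if (attempt == 20L) stop(res)
  }

  # slot assignment: random within session, then order-constrained per image
  slot_image <- integer(n_slots)      # 0 = unassigned
  slot_exposure <- integer(n_slots)
  session_of_slot <- rep(seq_len(S), each = per_session)
  for (s in seq_len(S)) {
    members <- which(sess == s, arr.ind = TRUE)   # (image, exposure) pairs
    if (nrow(members) == 0L) next
    slots_here <- which(session_of_slot == s)
    chosen <- if (length(slots_here) == 1L) slots_here
              else sample(slots_here, nrow(members))
    slot_image[chosen] <- members[, 1L]
    slot_exposure[chosen] <- members[, 2L]
  }
  # within an image, make exposure index follow slot (onset) order
  for (i in seq_len(params$n_images)) {
    slots_i <- which(slot_image == i)
    slots_i <- sort(slots_i)
    slot_exposure[slots_i] <- seq_along(slots_i)
  }
  # fillers occupy leftover slots
  fill_slots <- which(slot_image == 0L)
  slot_is_filler <- slot_image == 0L
  if (length(fill_slots) > 0L) {
    slot_image[fill_slots] <- params$n_images + seq_along(fill_slots)
    slot_exposure[fill_slots] <- 1L
  }

  slot <- seq_len(n_slots)
  within_session <- (slot - 1L) %% per_session
  run <- within_session %/% Tr + 1L
  trial <- within_session %% Tr + 1L
  onset <- (session_of_slot - 1L) * params$session_gap_s +
    within_session * params$trial_duration_s
  image_id <- ifelse(slot_is_filler,
                     sprintf("fil%04d", slot_image - params$n_images),
                     sprintf("img%04d", slot_image))
  tibble::tibble(
    participant_id = sprintf("sub%02d", participant),
    session = session_of_slot,
    run = run,
    trial = trial,
    onset = onset,
    image_id = image_id,
    exposure = slot_exposure,
    is_filler = slot_is_filler
  )
}
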