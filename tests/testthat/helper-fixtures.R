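# Hand-built fixtures: a one-participant event table where run membership of
# every exposure is chosen explicitly, plus a pattern store of random voxel
# vectors aligned to it.

# events for `n_images` images given a matrix of (session, run) per exposure;
# trials are laid out chronologically in blocks of `per_run` trials per run
toy_events <- function(placement, runs_per_session = 3, trials_per_run = 12,
                       pid = "sub01") {
  n_images <- nrow(placement)
  sessions <- sort(unique(c(placement[, c(1, 3, 5)])))
  slots <- expand.grid(trial = seq_len(trials_per_run),
                       run = seq_len(runs_per_session),
                       session = seq_len(max(sessions)))
  slots <- slots[order(slots$session, slots$run, slots$trial), ]
  slots$onset <- (slots$session - 1) * 86400 +
    ((slots$run - 1) * trials_per_run + (slots$trial - 1)) * 4
  slots$image_id <- NA_character_
  slots$exposure <- NA_integer_
  used <- rep(FALSE, nrow(slots))
  for (i in seq_len(n_images)) {
    for (e in 1:3) {
      s <- placement[i, 2 * e - 1]
      r <- placement[i, 2 * e]
      cand <- which(slots$session == s & slots$run == r & !used)
      stopifnot(length(cand) > 0)
      k <- cand[1L]
      used[k] <- TRUE
      slots$image_id[k] <- sprintf("img%02d", i)
      slots$exposure[k] <- e
    }
  }
  keep <- !is.na(slots$image_id)
  tibble::tibble(participant_id = pid,
                 session = as.integer(slots$session[keep]),
                 run = as.integer(slots$run[keep]),
                 trial = as.integer(slots$trial[keep]),
                 onset = slots$onset[keep],
                 image_id = slots$image_id[keep],
                 exposure = as.integer(slots$exposure[keep]),
                 is_filler = FALSE)
}

toy_store <- function(events, roi = "CA1", n_voxels = 20, seed = 1) {
  pid <- unique(events$participant_id)
  withr::with_seed(seed, {
    mats <- lapply(pid, function(p) {
      n <- sum(events$participant_id == p)
      stats::setNames(list(matrix(stats::rnorm(n * n_voxels), n, n_voxels)),
                      roi)
    })
  })
  names(mats) <- pid
  pattern_store(events, mats)
}

# small full simulation used by several integration tests
small_sim <- function(seed = 1, n_participants = 3, n_images = 60,
                      rois = list(roi_spec("CA1", n_voxels = 60,
                                           role = "precision")),
                      truth = truth_params()) {
  simulate_experiment(
    design_params(n_participants = n_participants, n_sessions = 6,
                  runs_per_session = 4,
                  trials_per_run = max(10L, ceiling(3.9 * n_images / 24)),
                  n_images = n_images),
    rois = rois, truth = truth, seed = seed, n_novel = 30)
}

# eight-candidate foil-membership fixture shared across test files
toy_summary <- function() {
  # target: E1 in session 2 run 1, E2 in session 4 run 2; eight candidates
  tibble::tibble(
    image_id = c("tgt", sprintf("c%d", 1:8)),
    e1_session = c(2, 2, 2, 2, 2, 3, 2, 2, 2),
    e1_run     = c(1, 2, 3, 2, 1, 2, 2, 2, 2),
    e2_session = c(4, 4, 4, 4, 4, 4, 5, 4, 4),
    e2_run     = c(2, 1, 3, 1, 1, 1, 1, 2, 1),
    cr_e1      = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    hit_e2     = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    hit_e3     = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE))
}

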