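test_that("minimal design packs every image three times in onset order", {
  p <- design_params(n_participants = 1, n_sessions = 1, runs_per_session = 1,
                     trials_per_run = 6, n_images = 2, seed = 5)
  ev <- generate_design(p)
  expect_equal(nrow(ev), 6L)
  expect_false(any(ev$is_filler))
  for (img in unique(ev$image_id)) {
    d <- ev[ev$image_id == img, ]
    expect_equal(sort(d$exposure), 1:3)
    expect_equal(length(unique(d$onset)), 3L)
    o <- d$onset[order(d$exposure)]
    expect_true(all(diff(o) > 0))
  }
})

test_that("design generation is deterministic given the seed", {
  p <- design_params(n_participants = 2, n_sessions = 4, runs_per_session = 3,
                     trials_per_run = 8, n_images = 20, seed = 42)
  expect_identical(generate_design(p), generate_design(p))
  p2 <- p
  p2$seed <- 43L
  expect_false(identical(generate_design(p), generate_design(p2)))
})

test_that("infeasible packings raise a capacity error naming the constraint", {
  expect_error(design_params(n_sessions = 1, runs_per_session = 1,
                             trials_per_run = 5, n_images = 2),
               "infeasible packing")
})

test_that("within-session repeat fraction matches the configured rate", {
  # among E1->E2 transitions whose E1 session still allows a later session,
  # the same-session probability is the configured Bernoulli rate
  p_within <- 0.3
  same <- 0L
  eligible <- 0L
  for (s in 1:20) {
    p <- design_params(n_participants = 1, n_sessions = 10,
                       runs_per_session = 5, trials_per_run = 15,
                       n_images = 150, p_within_session_repeat = p_within,
                       seed = 7000 + s)
    ev <- generate_design(p)
    ev <- ev[!ev$is_filler, ]
    for (d in split(ev, ev$image_id)) {
      s12 <- d$session[order(d$exposure)][1:2]
      if (s12[1] < 10) {
        eligible <- eligible + 1L
        same <- same + as.integer(s12[1] == s12[2])
      }
    }
  }
  se <- sqrt(p_within * (1 - p_within) / eligible)
  expect_lt(abs(same / eligible - p_within), 4 * se + 0.005)
})

test_that("patterns collapse to the image signal when context and noise vanish", {
  p <- design_params(n_participants = 1, n_sessions = 3, runs_per_session = 2,
                     trials_per_run = 10, n_images = 15, seed = 3)
  ev <- generate_design(p)
  roi <- roi_spec("A", n_voxels = 10, context_signal_sd = 0,
                  session_signal_sd = 0, noise_sd = 0, role = "none")
  pg <- generate_patterns(ev, list(roi), truth_params(), seed = 4)
  idx <- pg$store$index[["sub01"]]
  mat <- pg$store$patterns[["sub01"]][["A"]]
  for (img in unique(idx$image_id[!idx$is_filler])) {
    rows <- idx$row[idx$image_id == img]
    expect_equal(mat[rows[1], ], mat[rows[2], ])
    expect_equal(mat[rows[1], ], mat[rows[3], ])
    expect_equal(pattern_correlation(mat[rows[1], ] , mat[rows[2], ]), 1)
  }
})

test_that("context drift follows the closed-form OU autocorrelation", {
  # single session, no image/session signal: patterns are the OU context
  p <- design_params(n_participants = 1, n_sessions = 1, runs_per_session = 5,
                     trials_per_run = 100, n_images = 2, seed = 8)
  ev <- generate_design(p)
  tau <- 25
  roi <- roi_spec("A", n_voxels = 150, tau = tau, image_signal_sd = 0,
                  session_signal_sd = 0, noise_sd = 0, role = "none")
  pg <- generate_patterns(ev, list(roi), truth_params(), seed = 9)
  mat <- pg$store$patterns[["sub01"]][["A"]]
  # fillers are distinct images with image_signal_sd = 0, so every row is c_t
  for (lag in c(5, 25, 60)) {
    pairs <- seq_len(nrow(mat) - lag)
    emp <- mean(vapply(pairs, function(t)
      pattern_correlation(mat[t, ], mat[t + lag, ]), numeric(1)))
    expect_lt(abs(emp - exp(-lag / tau)), 0.06)
  }
})

test_that("full reinstatement with no noise re-expresses E1 exactly", {
  p <- design_params(n_participants = 1, n_sessions = 3, runs_per_session = 2,
                     trials_per_run = 10, n_images = 12, seed = 12)
  ev <- generate_design(p)
  roi <- roi_spec("A", n_voxels = 12, image_signal_sd = 0,
                  session_signal_sd = 0, noise_sd = 0, role = "precision")
  tp <- truth_params(rho_fixed = 1)
  pg <- generate_patterns(ev, list(roi), tp, seed = 13)
  idx <- pg$store$index[["sub01"]]
  mat <- pg$store$patterns[["sub01"]][["A"]]
  for (img in unique(idx$image_id[!idx$is_filler])) {
    rows <- idx$row[idx$image_id == img][order(idx$exposure[idx$image_id == img])]
    expect_equal(mat[rows[2], ], mat[rows[1], ], tolerance = 1e-12)
    expect_equal(mat[rows[3], ], mat[rows[1], ], tolerance = 1e-12)
  }
})

test_that("timeline estimates are exact when estimate noise vanishes", {
  sim <- small_sim(seed = 21, truth = truth_params(sigma0 = 0))
  # all-zero errors trigger the degenerate-split warning by construction
  sc <- suppressWarnings(score_behavior(sim$final_test, sim$events,
                                        require_all_correct = FALSE))
  expect_true(all(sc$temporal_error == 0))
})

test_that("estimate error is independent of reinstatement when uncoupled", {
  p <- design_params(n_participants = 1, n_sessions = 10,
                     runs_per_session = 10, trials_per_run = 35,
                     n_images = 1000, seed = 31)
  ev <- generate_design(p)
  roi <- roi_spec("A", n_voxels = 2, role = "precision")
  tp <- truth_params(kappa_precision = 0)
  pg <- generate_patterns(ev, list(roi), tp, seed = 32)
  ft <- generate_behavior(ev, pg$truth, seed = 33)
  old <- ft[ft$item_type == "old", ]
  err <- abs(old$timeline_estimate -
               old$actual_E1_onset / max(old$actual_E1_onset))
  lat <- pg$truth$image
  rho <- lat$rho[match(old$image_id, lat$image_id)]
  expect_lt(abs(cor(rho, err)), 0.1)
})

test_that("behavior generation is deterministic given the seed", {
  sim <- small_sim(seed = 41)
  a <- generate_behavior(sim$events, sim$truth, seed = 5)
  b <- generate_behavior(sim$events, sim$truth, seed = 5)
  expect_identical(a, b)
})

test_that("behavior generation rejects designs with missing exposures", {
  sim <- small_sim(seed = 51)
  broken <- sim$events[-which(!sim$events$is_filler)[1], ]
  expect_error(generate_behavior(broken, sim$truth, seed = 1),
               "lack 3 exposures")
})
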