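test_that("midranks order values and average ties", {
  expect_equal(rank_transform(c(10, 500, 200)), c(1, 3, 2))
  expect_equal(rank_transform(c(5, 5, 9)), c(1.5, 1.5, 3))
  expect_error(rank_transform(7), "at least 2")
  expect_error(rank_transform(c(1, NA)), "finite")
})

test_that("midranks match the counting oracle and conserve the rank sum", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      x <- sample(round(rnorm(50), 1))   # rounding forces ties
      r <- rank_transform(x)
      expect_equal(r, oracle_midrank(x))
      expect_equal(sum(r), 50 * 51 / 2)
    }
  })
})

test_that("temporal error is the elementwise absolute rank difference", {
  expect_equal(temporal_error(c(1, 2, 3), c(1, 2, 3)), c(0, 0, 0))
  expect_equal(temporal_error(c(3, 2, 1), c(1, 2, 3)), c(2, 0, 2))
  expect_error(temporal_error(1:3, 1:4), "equal length")
})

test_that("error is invariant to monotone transforms of raw estimates", {
  withr::with_seed(12, {
    est <- runif(40)
    act <- runif(40)
    e1 <- temporal_error(rank_transform(est), rank_transform(act))
    e2 <- temporal_error(rank_transform(qlogis(est)), rank_transform(act))
    e3 <- temporal_error(rank_transform(est^3), rank_transform(act))
    expect_equal(e1, e2)
    expect_equal(e1, e3)
  })
})

test_that("median split labels items below the median as high precision", {
  expect_equal(label_precision(c(0, 1, 2, 3)), c("high", "high", "low", "low"))
  # ties with the median go to 'low' under the >= rule
  expect_equal(label_precision(c(0, 1, 1, 2)), c("high", "low", "low", "low"))
  expect_warning(out <- label_precision(rep(2, 6)), "degenerate")
  expect_equal(out, rep("low", 6))
})

test_that("median split imbalance is bounded by the number of median ties", {
  withr::with_seed(13, {
    for (rep in 1:20) {
      e <- sample(0:10, 30, replace = TRUE)
      lab <- label_precision(e)
      # #(x <= med) >= n/2 implies the imbalance is at most twice the
      # number of values tied with the median
      n_tied <- sum(e == median(e))
      expect_lte(abs(sum(lab == "high") - sum(lab == "low")), 2 * n_tied)
      # brute-force check of the labelling rule itself
      expect_equal(lab, ifelse(e < median(e), "high", "low"))
    }
  })
})

test_that("perfect temporal memory yields zero observed error and small p", {
  ct <- participant_chance_test(1:20, 1:20, n_perm = 1000, seed = 2)
  expect_equal(ct$observed_stat, 0)
  expect_equal(ct$p_value, mean(ct$null_values <= 0))
  expect_lt(ct$p_value, 0.05)
  expect_length(ct$null_values, 1000)
})

test_that("chance-test p-values are uniform when estimates are uninformative", {
  ps <- withr::with_seed(14, {
    vapply(1:200, function(i) {
      est <- sample(30)
      act <- sample(30)
      participant_chance_test(est, act, n_perm = 200, seed = 1000 + i)$p_value
    }, numeric(1))
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("lags are log-seconds from the experiment's reference points", {
  ev <- tibble::tibble(
    participant_id = "s01",
    session = c(1L, 2L, 2L, 3L),
    run = c(1L, 1L, 2L, 1L),
    trial = 1L,
    onset = c(0, 86400, 86400 + 400, 2 * 86400),
    image_id = c("f1", "img01", "img01", "img01"),
    exposure = c(1L, 1L, 2L, 3L),
    is_filler = c(TRUE, FALSE, FALSE, FALSE))
  fin <- 2 * 86400 + 3600
  lags <- compute_lags(ev, final_test_onset = fin)
  expect_equal(lags$lag0, log(86400), tolerance = 1e-12)
  expect_equal(lags$lag0, 11.3668, tolerance = 1e-4)
  expect_equal(lags$lag1, log(400), tolerance = 1e-12)
  expect_equal(lags$lag2, log(86400 - 400), tolerance = 1e-12)
  expect_equal(lags$lag3, log(3600), tolerance = 1e-12)
})

test_that("lag floor keeps the first trial's lag defined at zero", {
  p <- design_params(n_participants = 1, n_sessions = 2, runs_per_session = 2,
                     trials_per_run = 9, n_images = 10, seed = 6)
  ev <- generate_design(p)
  lags <- compute_lags(ev, final_test_onset = max(ev$onset) + 1000)
  first_img <- ev$image_id[which.min(ev$onset)]
  if (first_img %in% lags$image_id) {
    expect_equal(lags$lag0[lags$image_id == first_img], 0)
  }
  expect_true(all(is.finite(as.matrix(lags[, c("lag0", "lag1", "lag2",
                                               "lag3")]))))
  # interval additivity: exp(lag1) + exp(lag2) reproduces the E1->E3 span
  # exactly whenever neither interval hit the floor
  ev3 <- ev[!ev$is_filler, ]
  spans <- vapply(split(ev3, ev3$image_id), function(d) {
    o <- d$onset[order(d$exposure)]
    o[3] - o[1]
  }, numeric(1))
  spans <- spans[lags$image_id]
  above_floor <- exp(lags$lag1) > 1 & exp(lags$lag2) > 1
  expect_true(all(abs((exp(lags$lag1) + exp(lags$lag2) -
                         spans))[above_floor] < 1e-6))
})

test_that("chronology violations in the event table are rejected", {
  pl <- rbind(c(1, 1, 1, 2, 2, 1))
  ev <- toy_events(pl)
  ev$onset[ev$exposure == 2] <- ev$onset[ev$exposure == 3] + 10
  expect_error(compute_lags(ev, final_test_onset = 1e7),
               "not chronological")
})

test_that("d-prime follows the normal-quantile closed form", {
  mk <- function(pid, old_conf, new_conf) {
    tibble::tibble(participant_id = pid,
                   image_id = sprintf("i%03d", seq_along(c(old_conf, new_conf))),
                   item_type = rep(c("old", "novel"),
                                   c(length(old_conf), length(new_conf))),
                   confidence = as.integer(c(old_conf, new_conf)))
  }
  # 9/10 old and 1/10 novel called old: d' = z(.9) - z(.1)
  ft <- rbind(mk("a", c(rep(6, 9), 1), c(rep(1, 9), 6)),
              mk("b", c(rep(6, 9), 1), c(rep(1, 9), 6)))
  rs <- recognition_summary(ft)
  expect_equal(rs$per_participant$d_prime,
               rep(qnorm(0.9) - qnorm(0.1), 2), tolerance = 1e-10)
  expect_equal(qnorm(0.9) - qnorm(0.1), 2.5631, tolerance = 1e-4)
  # equal rates give d' = 0
  ft0 <- rbind(mk("a", c(rep(6, 5), rep(1, 5)), c(rep(6, 5), rep(1, 5))),
               mk("b", c(rep(6, 5), rep(1, 5)), c(rep(6, 5), rep(1, 5))))
  rs0 <- recognition_summary(ft0)
  expect_equal(rs0$per_participant$d_prime, c(0, 0), tolerance = 1e-10)
})

test_that("paired recognition t-test is calibrated under an i.i.d. null", {
  ps <- withr::with_seed(15, {
    vapply(1:200, function(i) {
      ft <- do.call(rbind, lapply(sprintf("p%02d", 1:8), function(pid) {
        tibble::tibble(participant_id = pid,
                       image_id = sprintf("i%03d", 1:80),
                       item_type = rep(c("old", "novel"), each = 40),
                       confidence = sample(1:6, 80, replace = TRUE))
      }))
      recognition_summary(ft)$paired_t$p
    }, numeric(1))
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("accuracy model recovers identity and planted slopes", {
  # identity data: slope exactly 1
  d <- do.call(rbind, lapply(1:3, function(g)
    tibble::tibble(participant_id = sprintf("p%d", g),
                   est_rank = 1:30, act_rank = 1:30)))
  fit <- suppressWarnings(fit_accuracy_model(d))
  slope <- fit$coefficients[fit$coefficients$term == "act_rank", ]
  expect_equal(slope$estimate, 1, tolerance = 1e-6)

  # planted slope 0.5 on the rank scale: CI covers truth in most replicates
  hits <- withr::with_seed(16, {
    vapply(1:50, function(i) {
      d <- do.call(rbind, lapply(1:6, function(g) {
        act <- sample(40)
        est <- 20 + 0.5 * act + rnorm(40, sd = 6)
        tibble::tibble(participant_id = sprintf("p%d", g),
                       est_rank = est, act_rank = act)
      }))
      fit <- suppressWarnings(fit_accuracy_model(d))
      co <- fit$coefficients[fit$coefficients$term == "act_rank", ]
      co$ci_lower <= 0.5 && 0.5 <= co$ci_upper
    }, logical(1))
  })
  expect_gte(mean(hits), 0.8)
})

test_that("accuracy-slope CI covers zero when estimates are uninformative", {
  hits <- withr::with_seed(17, {
    vapply(1:50, function(i) {
      d <- do.call(rbind, lapply(1:6, function(g)
        tibble::tibble(participant_id = sprintf("p%d", g),
                       est_rank = sample(40), act_rank = sample(40))))
      fit <- suppressWarnings(fit_accuracy_model(d))
      co <- fit$coefficients[fit$coefficients$term == "act_rank", ]
      co$ci_lower <= 0 && 0 <= co$ci_upper
    }, logical(1))
  })
  expect_gte(mean(hits), 0.86)
})
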