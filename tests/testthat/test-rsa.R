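test_that("pattern correlation matches the direct formula and its contracts", {
  expect_equal(pattern_correlation(c(1, 2, 5), c(1, 2, 5)), 1)
  expect_equal(pattern_correlation(c(1, -1, 1, -1), c(1, 1, -1, -1)), 0)
  withr::with_seed(21, {
    for (rep in 1:20) {
      a <- rnorm(5)
      b <- rnorm(5)
      expect_equal(pattern_correlation(a, b), oracle_pearson(a, b),
                   tolerance = 1e-12)
    }
  })
  expect_error(pattern_correlation(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(pattern_correlation(1:3, 1:4), "equal length")
})

test_that("correlation is invariant to shift and positive rescaling", {
  withr::with_seed(22, {
    a <- rnorm(30)
    b <- rnorm(30)
    r <- pattern_correlation(a, b)
    expect_equal(pattern_correlation(a + 7, b), r, tolerance = 1e-12)
    expect_equal(pattern_correlation(a * 3.2, b - 1), r, tolerance = 1e-12)
  })
})

test_that("Fisher transform is atanh: closed form, oddness, domain", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  expect_equal(fisher_z(0.5), 0.5 * log(1.5 / 0.5), tolerance = 1e-12)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(-r), -fisher_z(r), tolerance = 1e-12)
  expect_error(fisher_z(1), "\\|r\\| < 1")
  expect_error(fisher_z(-1.2), "\\|r\\| < 1")
})

test_that("cross-run rule flags exactly the same-run exposure pairs", {
  # img01: E1/E2 same run -> pair (1,2) invalid; (2,3), (1,3) valid
  pl <- rbind(c(1, 1, 1, 1, 2, 1),
              c(1, 1, 1, 2, 2, 1),
              c(1, 2, 2, 1, 2, 2))
  ev <- toy_events(pl)
  store <- toy_store(ev, seed = 5)
  st <- exposure_similarities(ev, store, "CA1")
  r1 <- st[st$image_id == "img01", ]
  expect_equal(c(r1$valid12, r1$valid23, r1$valid13), c(FALSE, TRUE, TRUE))
  expect_true(is.na(r1$z12))
  expect_equal(r1$mean_z, mean(c(r1$z23, r1$z13)))
  # img02 and img03: all exposures in distinct runs -> 3 valid pairs
  expect_equal(st$n_valid[st$image_id == "img02"], 3)
  expect_equal(st$n_valid[st$image_id == "img03"], 3)
  expect_lte(max(st$n_valid), 3)
})

test_that("similarities equal direct correlations of the stored patterns", {
  pl <- rbind(c(1, 1, 1, 2, 2, 1),
              c(1, 2, 2, 1, 2, 2))
  ev <- toy_events(pl)
  store <- toy_store(ev, seed = 6)
  st <- exposure_similarities(ev, store, "CA1")
  idx <- store$index[["sub01"]]
  mat <- store$patterns[["sub01"]][["CA1"]]
  for (img in c("img01", "img02")) {
    rows <- idx$row[idx$image_id == img][order(idx$exposure[idx$image_id == img])]
    expect_equal(st$z12[st$image_id == img],
                 atanh(oracle_pearson(mat[rows[1], ], mat[rows[2], ])),
                 tolerance = 1e-12)
  }
})

test_that("high/low group statistic matches a group-by-mean oracle", {
  sim_tab <- tibble::tibble(
    participant_id = rep(c("a", "b", "c"), each = 4),
    image_id = rep(sprintf("i%d", 1:4), 3),
    mean_z = c(0.9, 0.8, 0.1, 0.2,  0.7, 0.6, 0.3, 0.2,  0.5, 0.4, 0.1, 0.0),
    z12 = NA, z23 = NA, z13 = NA)
  labels <- tibble::tibble(
    participant_id = sim_tab$participant_id,
    image_id = sim_tab$image_id,
    precision_label = rep(c("high", "high", "low", "low"), 3))
  hl <- high_low_permutation(sim_tab, labels, pair = "mean", n_perm = 50,
                             seed = 3)
  oracle <- mean(c(mean(c(0.9, 0.8)) - mean(c(0.1, 0.2)),
                   mean(c(0.7, 0.6)) - mean(c(0.3, 0.2)),
                   mean(c(0.5, 0.4)) - mean(c(0.1, 0.0))))
  expect_equal(hl$observed_stat, oracle, tolerance = 1e-12)
  expect_length(hl$null_values, 50)
})

test_that("extreme separation of the label classes yields p = 0", {
  withr::with_seed(23, {
    sim_tab <- tibble::tibble(
      participant_id = rep(sprintf("p%d", 1:4), each = 20),
      image_id = rep(sprintf("i%02d", 1:20), 4),
      mean_z = rnorm(80, sd = 0.01),
      z12 = NA, z23 = NA, z13 = NA)
    labels <- tibble::tibble(
      participant_id = sim_tab$participant_id,
      image_id = sim_tab$image_id,
      precision_label = rep(rep(c("high", "low"), each = 10), 4))
    sim_tab$mean_z[labels$precision_label == "high"] <-
      sim_tab$mean_z[labels$precision_label == "high"] + 100
  })
  hl <- high_low_permutation(sim_tab, labels, n_perm = 500, seed = 4)
  expect_equal(hl$p_value, 0)
})

test_that("permutation p is invariant to within-participant image relabeling", {
  withr::with_seed(24, {
    sim_tab <- tibble::tibble(
      participant_id = rep(sprintf("p%d", 1:3), each = 12),
      image_id = rep(sprintf("i%02d", 1:12), 3),
      mean_z = rnorm(36), z12 = NA, z23 = NA, z13 = NA)
    labels <- tibble::tibble(
      participant_id = sim_tab$participant_id,
      image_id = sim_tab$image_id,
      precision_label = sample(rep(c("high", "low"), 18)))
  })
  p1 <- high_low_permutation(sim_tab, labels, n_perm = 300, seed = 9)$p_value
  # relabel images consistently in both tables (rows keep their pairing)
  relab <- function(x) sprintf("j%s", x$image_id)
  sim_tab2 <- sim_tab
  labels2 <- labels
  sim_tab2$image_id <- relab(sim_tab)
  labels2$image_id <- relab(labels)
  p2 <- high_low_permutation(sim_tab2, labels2, n_perm = 300, seed = 9)$p_value
  expect_equal(p1, p2)
})

test_that("high/low permutation p is uniform under a true null", {
  ps <- withr::with_seed(25, {
    vapply(1:200, function(i) {
      sim_tab <- tibble::tibble(
        participant_id = rep(sprintf("p%d", 1:6), each = 30),
        image_id = rep(sprintf("i%02d", 1:30), 6),
        mean_z = rnorm(180), z12 = NA, z23 = NA, z13 = NA)
      labels <- tibble::tibble(
        participant_id = sim_tab$participant_id,
        image_id = sim_tab$image_id,
        precision_label = as.vector(replicate(6, sample(
          rep(c("high", "low"), 15)))))
      high_low_permutation(sim_tab, labels, n_perm = 200,
                           seed = 3000 + i)$p_value
    }, numeric(1))
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.05)
})
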