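test_that("midline distance and pixel calibration follow the screen geometry", {
  expect_equal(distance_from_center_px(34), 366)
  expect_equal(distance_from_center_px(400), 0)
  expect_equal(distance_from_center_px(766), 366)
  expect_equal(px_to_mm(1), 0.29)
  expect_equal(px_to_mm(0), 0)
  expect_equal(px_to_mm(366), 106.14)
  expect_equal(center_distance_mm(34), 106.14)
  expect_error(distance_from_center_px(800), "range")
  expect_error(distance_from_center_px(-1), "range")
  expect_error(px_to_mm(-3), "nonnegative")
})

test_that("successive distances use the hypotenuse and honour the inclusion rule", {
  tr <- toy_session(rep("exploit", 2), rep("left", 2), c(0, 3), c(0, 4))
  p <- successive_euclidean(tr)
  expect_equal(p$dist_mm, 5 * 0.29)

  p6 <- successive_euclidean(make_fixture("side_switch_6"))
  expect_equal(nrow(p6), 5)
  expect_equal(sum(!p6$included), 1)
  expect_equal(p6$exclusion_reason[3], "side_transition")

  same <- toy_session(rep("exploit", 4), rep("left", 4), rep(100, 4),
                      rep(200, 4))
  expect_true(all(successive_euclidean(same)$dist_mm == 0))

  no_state <- same
  no_state$state <- NA
  expect_error(successive_euclidean(no_state), "state")
})

test_that("exclusion accounting is an exact partition of the pairs", {
  set.seed(3)
  co <- generate_cohort(cohort_config(n_per_sex = 2, n_sessions = 2), seed = 3)
  tr <- co$trials
  tr$state <- tr$true_state
  p <- successive_euclidean(tr)
  s <- exclusion_summary(p)
  expect_equal(s$n_included + s$n_excluded, s$n_pairs)
  expect_equal(s$n_side_only + s$n_state_only + s$n_both, s$n_excluded)
  expect_equal(s$n_pairs, nrow(tr) - 2 * 2 * 2)  # N-1 pairs per session
  expect_true(all(p$dist_mm >= 0))
  # pair distances obey the triangle inequality on consecutive triples
  one <- tr[tr$mouse_id == tr$mouse_id[1] & tr$session == 1, ]
  d <- function(i, j) sqrt((one$x[i] - one$x[j])^2 + (one$y[i] - one$y[j])^2)
  for (i in 1:20) expect_lte(d(i, i + 2), d(i, i + 1) + d(i + 1, i + 2) + 1e-9)
})

test_that("Mahalanobis distances match direct matrix algebra and its degeneracies", {
  pts <- cbind(c(0, 1, 2, 0, 1, 2), c(0, 0, 1, 2, 2, 1))
  expect_equal(mahalanobis_from_centroid(pts), oracle_mahalanobis(pts),
               tolerance = 1e-12)
  # a point at the centroid scores zero
  sym <- rbind(c(1, 1), c(-1, 1), c(1, -1), c(-1, -1), c(0, 0))
  expect_equal(mahalanobis_from_centroid(sym)[5], 0)
  # isotropic clouds reduce to scaled Euclidean distance from the centroid
  set.seed(8)
  iso <- cbind(rnorm(500), rnorm(500))
  m <- mahalanobis_from_centroid(iso)
  eu <- sqrt(rowSums(sweep(iso, 2, colMeans(iso))^2))
  expect_gt(cor(m, eu), 0.99)
  # collinear clouds are flagged degenerate
  expect_null(mahalanobis_from_centroid(cbind(1:5, 2 * (1:5))))
  tr <- toy_session(rep("exploit", 5), rep("left", 5), c(1:5), 2 * c(1:5))
  out <- add_mahalanobis(tr)
  expect_true(all(is.na(out$mahal)))
  expect_gt(length(attr(out, "skipped_groups")), 0)
})

test_that("previous-outcome conditioning drops first trials and flags empty groups", {
  tr <- toy_session(rep("exploit", 5), rep("left", 5), 1:5, 1:5,
                    rewards = rep(1L, 5))
  cond <- condition_on_prev_reward(tr)
  expect_equal(nrow(cond), 4)
  expect_true(all(cond$prev_reward == "rewarded"))
  expect_equal(attr(cond, "empty_groups"), "nonrewarded")
})

test_that("planted post-reward shrinkage is detected and vanishes under label shuffling", {
  hits <- 0
  for (seed in 1:10) {
    co <- generate_cohort(cohort_config(n_per_sex = 3, n_sessions = 2),
                          seed = seed)
    tr <- co$trials
    tr$state <- tr$true_state
    p <- successive_euclidean(tr)
    p <- p[p$included, ]
    diff_obs <- mean(p$dist_mm[p$prev_reward == 1]) -
      mean(p$dist_mm[p$prev_reward == 0])
    if (diff_obs < 0) hits <- hits + 1
    if (seed == 1) {
      set.seed(99)
      for (k in 1:5) {
        sh <- sample(p$prev_reward)
        diff_sh <- mean(p$dist_mm[sh == 1]) - mean(p$dist_mm[sh == 0])
        expect_lt(abs(diff_sh), abs(diff_obs))
      }
    }
  }
  expect_gte(hits, 9)
})

test_that("latency summaries aggregate per mouse and state, exploit faster when planted", {
  tr <- toy_session(c("explore", "exploit", "exploit"), rep("left", 3),
                    1:3, 1:3)
  ls <- latency_summary(tr)
  expect_equal(ls$mean_rt, c(1, 1))
  single <- tr[1, ]
  expect_equal(latency_summary(single)$mean_rt, 1)
  bad <- tr
  bad$rt[1] <- -1
  expect_error(latency_summary(bad), "negative")

  hits <- 0
  for (seed in 1:10) {
    co <- generate_cohort(cohort_config(n_per_sex = 3, n_sessions = 2),
                          seed = 100 + seed)
    tr <- co$trials
    tr$state <- tr$true_state
    ls <- latency_summary(tr)
    m <- tapply(ls$mean_rt, ls$state, mean)
    if (m[["exploit"]] < m[["explore"]]) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
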