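test_that("episodes are delimited exactly at explore/exploit transitions", {
  tr <- toy_session(c("explore", "explore", "exploit", "exploit", "explore"),
                    rep("left", 5), 1:5, 1:5)
  b <- segment_bouts(tr)
  expect_equal(length(unique(b$episode)), 3)
  counts <- bout_counts(tr)
  expect_equal(counts$n_explore, 2)
  expect_equal(counts$n_exploit, 1)

  const <- toy_session(rep("exploit", 8), rep("left", 8), 1:8, 1:8)
  cc <- bout_counts(const)
  expect_equal(c(cc$n_explore, cc$n_exploit), c(0, 1))

  # side-split bout spans partition the session without overlap
  mixed <- toy_session(c(rep("explore", 4), rep("exploit", 4)),
                       c("left", "right", "left", "right", rep("left", 4)),
                       1:8, 1:8)
  bb <- segment_bouts(mixed)
  expect_equal(sum(bb$n_trials), 8)
  expect_error(segment_bouts(transform(mixed, state = NA)), "state")
})

test_that("explore and exploit episode counts differ by at most one", {
  set.seed(4)
  for (k in 1:20) {
    states <- ifelse(rbinom(100, 1, 0.5) == 1, "explore", "exploit")
    tr <- toy_session(states, rep("left", 100), 1:100, 1:100)
    cc <- bout_counts(tr)
    expect_lte(abs(cc$n_explore - cc$n_exploit), 1)
  }
})

test_that("centroid shifts equal the Euclidean distance between recomputed centroids", {
  tr <- toy_session(c("exploit", "exploit", "explore", "exploit", "exploit"),
                    rep("left", 5), c(0, 0, 50, 3, 3), c(0, 0, 50, 4, 4))
  b <- segment_bouts(tr)
  sh <- centroid_shift_distances(b)
  ex <- sh[sh$state == "exploit", ]
  expect_equal(ex$shift_mm, 5 * 0.29)
  # identical centroids give zero shift
  tr2 <- toy_session(c("exploit", "explore", "exploit"), rep("left", 3),
                     c(10, 99, 10), c(20, 99, 20))
  sh2 <- centroid_shift_distances(segment_bouts(tr2))
  expect_equal(sh2$shift_mm[sh2$state == "exploit"], 0)
  # compositional oracle on a generated session
  co <- generate_cohort(cohort_config(n_per_sex = 1, n_sessions = 1), seed = 6)
  tr3 <- co$trials
  tr3 <- tr3[tr3$mouse_id == "F01", ]
  tr3$state <- tr3$true_state
  b3 <- segment_bouts(tr3)
  g <- b3[b3$state == "exploit" & b3$side == "left", ]
  g <- g[order(g$episode), ]
  if (nrow(g) >= 2) {
    g$cx <- NA_real_
    g$cy <- NA_real_
    for (i in seq_len(nrow(g))) {
      idx <- tr3$trial >= g$trial_start[i] & tr3$trial <= g$trial_end[i] &
        tr3$side == "left"
      g$cx[i] <- mean(tr3$x[idx])
      g$cy[i] <- mean(tr3$y[idx])
    }
    want <- 0.29 * sqrt(diff(g$cx)^2 + diff(g$cy)^2)
    got <- centroid_shift_distances(b3)
    got <- got[got$state == "exploit" & got$side == "left", ]
    expect_equal(got$shift_mm, want, tolerance = 1e-9)
  }
})

test_that("shoelace area and perimeter match hand geometry and ignore orientation", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  g <- polygon_area_perimeter(sq)
  expect_equal(g$area, 1)
  expect_equal(g$perimeter, 4)
  tri <- cbind(c(0, 3, 0), c(0, 0, 4))
  g2 <- polygon_area_perimeter(tri)
  expect_equal(g2$area, 6)
  expect_equal(g2$perimeter, 12)
  g3 <- polygon_area_perimeter(tri[3:1, ])
  expect_equal(g3$area, 6)
  expect_equal(g3$perimeter, 12)
  expect_error(polygon_area_perimeter(tri[1:2, ]), "3")
})

test_that("the density boundary recovers a known uniform support", {
  set.seed(12)
  r <- bout_density_boundary(runif(10000, 0, 20), runif(10000, 0, 20),
                             units = "mm")
  expect_false(r$degenerate)
  expect_lt(abs(r$area_mm2 - 400) / 400, 0.15)
  # coincident points are degenerate
  expect_true(bout_density_boundary(rep(5, 50), rep(5, 50))$degenerate)
  expect_true(bout_density_boundary(1:3, 1:3)$degenerate)
})

test_that("doubling the spatial scale quadruples area and doubles perimeter", {
  set.seed(13)
  x <- rnorm(4000, 0, 5); y <- rnorm(4000, 0, 5)
  r1 <- bout_density_boundary(x, y, units = "mm")
  r2 <- bout_density_boundary(2 * x, 2 * y, units = "mm")
  expect_gt(r2$area_mm2 / r1$area_mm2, 3.2)
  expect_lt(r2$area_mm2 / r1$area_mm2, 4.8)
  expect_gt(r2$perimeter_mm / r1$perimeter_mm, 1.7)
  expect_lt(r2$perimeter_mm / r1$perimeter_mm, 2.3)
})

test_that("member points lie inside the outer boundary and dispersion grows area", {
  set.seed(14)
  x <- rnorm(400, 100, 10); y <- rnorm(400, 100, 10)
  r <- bout_density_boundary(x, y, units = "mm")
  inside <- vapply(seq_along(x), function(i) {
    any(vapply(r$polygons, function(p)
      touchbandit:::point_in_polygon(x[i], y[i], p[, 1], p[, 2]), TRUE))
  }, TRUE)
  expect_gt(mean(inside), 0.98)

  areas <- function(sd) {
    vapply(1:20, function(k) {
      bout_density_boundary(rnorm(200, 0, sd), rnorm(200, 0, sd),
                            units = "mm")$area_mm2
    }, 0)
  }
  expect_gt(mean(areas(10)), mean(areas(5)))
})

test_that("the bout table keeps small bouts but withholds their geometry", {
  co <- generate_cohort(cohort_config(n_per_sex = 1, n_sessions = 1), seed = 9)
  tr <- co$trials
  tr$state <- tr$true_state
  b <- bout_table(tr)
  expect_true(all(b$n_trials >= 1))
  small <- b$n_trials < 5
  expect_true(all(is.na(b$area_mm2[small])))
  ok <- !b$degenerate
  expect_true(all(b$area_mm2[ok] >= 0))
  expect_true(all(b$perimeter_mm[ok] >= 0))
})
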