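test_that("feeding frequencies follow the session arithmetic and exclusions", {
  tabs <- tiny_tables(n_nests = 3L)
  tabs$sessions$duration_min <- c(90, 60, 45)
  tabs$nests$brood_unclear[3] <- TRUE
  # 15 landings in 90 min -> 10 per h
  extra <- tabs$landing_points[rep(1, 10), ]
  extra$point_id <- paste0("x", 1:10)
  extra$session_id <- tabs$sessions$session_id[1]
  extra$nest_id <- tabs$nests$nest_id[1]
  lp <- rbind(tabs$landing_points, extra)
  ff <- feeding_frequencies(tabs$sessions, lp, tabs$nests)
  r1 <- ff$records[ff$records$session_id == tabs$sessions$session_id[1], ]
  expect_equal(r1$per_h, 15 / 90 * 60)
  expect_equal(r1$per_h_chick, r1$per_h / 3)
  # identity per_h = per_h_chick * brood holds exactly for every session
  expect_equal(ff$records$per_h,
               ff$records$per_h_chick * ff$records$brood_size)
  # the unclear-brood nest is excluded entirely
  expect_false(tabs$nests$nest_id[3] %in% ff$records$nest_id)
  # sessions after sunset are excluded
  tabs$sessions$ended_before_sunset[2] <- FALSE
  ff2 <- feeding_frequencies(tabs$sessions, lp, tabs$nests)
  expect_false(tabs$sessions$session_id[2] %in% ff2$records$session_id)
  expect_equal(ff2$exclusions$sessions_after_sunset, 1L)
  # non-positive duration is an error
  tabs$sessions$duration_min[1] <- 0
  expect_error(feeding_frequencies(tabs$sessions, lp, tabs$nests),
               "duration")
})

test_that("flight distances are plain Euclidean point-nest distances", {
  tabs <- tiny_tables(n_nests = 1L, points_per_nest = 2L)
  tabs$landing_points$x <- c(tabs$nests$x[1] + 100, tabs$nests$x[1])
  tabs$landing_points$y <- tabs$nests$y[1]
  d <- flight_distances(tabs$nests, tabs$landing_points)
  expect_equal(d$distance_m, c(100, 0))
  # ambiguous points never enter
  tabs$landing_points$safe[1] <- FALSE
  d2 <- flight_distances(tabs$nests, tabs$landing_points)
  expect_equal(nrow(d2), 1L)
})

test_that("MCP95 peels outliers exactly as the hull oracle prescribes", {
  # 96 points on the corners of a 100-m square plus 4 distant outliers:
  # the outliers are peeled and the hull is the 1.0 ha square
  corners <- cbind(rep(c(0, 100), each = 2), rep(c(0, 100), 2))
  xy <- rbind(corners[rep(1:4, 24), ],
              cbind(c(1000, -1000, 1000, -1000),
                    c(1000, 1000, -1000, -1000)))
  m <- mcp95(xy, 0.95, 20L)
  expect_false(m$excluded)
  expect_equal(m$area_ha, 1.0, tolerance = 1e-9)
  expect_equal(m$n_retained, 96L)
  # fewer than 20 points -> excluded
  expect_true(mcp95(xy[1:19, ], 0.95, 20L)$excluded)
  # coincident points give area 0
  expect_equal(mcp95(matrix(5, 20, 2), 0.95, 20L)$area_ha, 0)
  # the retained fraction is monotone in area; fraction 1 is the full hull
  set.seed(44)
  pts <- cbind(rnorm(60, sd = 60), rnorm(60, sd = 60))
  areas <- vapply(c(0.5, 0.75, 0.95, 1), function(f)
    mcp95(pts, f, 20L)$area_ha, 0)
  expect_true(all(diff(areas) >= -1e-12))
  expect_equal(areas[4], convex_hull_area(pts) / 1e4, tolerance = 1e-12)
  # translation and rotation invariance
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- sweep(pts %*% R, 2, c(500, -300), "+")
  expect_equal(mcp95(moved, 0.95, 20L)$area_ha,
               mcp95(pts, 0.95, 20L)$area_ha, tolerance = 1e-6)
})

test_that("trend models run on synthetic data with sensible structure", {
  tr <- small_truth(23L, n_observed = 12L)
  sim <- simulate_dataset(tr)
  cfg <- study_config(rng_seed = 23L)
  fg <- pipeline_foraging(sim$data, cfg)
  expect_s3_class(fg$trends, "foraging_trends")
  for (m in fg$trends[c("frequency_per_h", "frequency_per_h_chick",
                        "distance")]) {
    expect_true(all(c("day", "chick_age", "daytime_min", "temperature",
                      "wind") %in% m$coefficients$term))
    expect_true(all(is.finite(m$coefficients$p_value)))
  }
  expect_true(all(c("hatch_day", "pct_before_noon") %in%
                    fg$trends$mcp$coefficients$term))
  # no seasonal structure in the generator: day effects are null in the
  # frequency models (single run, weak assertion: |t| below 3)
  per_h <- fg$trends$frequency_per_h$coefficients
  expect_lt(abs(per_h$t[per_h$term == "day"]), 3)
  # headline means are positive and finite
  expect_true(all(unlist(fg$means) > 0))
})
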