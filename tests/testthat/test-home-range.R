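make_points <- function(nest_id, d, angle = 0) {
  data.frame(point_id = paste0(nest_id, "_", seq_along(d)),
             session_id = paste0(nest_id, "_s"), nest_id = nest_id,
             x = 2000 + d * cos(angle), y = 2000 + d * sin(angle),
             safe = TRUE, habitat_type_observed = NA_character_,
             stringsAsFactors = FALSE)
}

one_nest <- function(id = "n1", x = 2000, y = 2000) {
  data.frame(nest_id = id, x = x, y = y, stringsAsFactors = FALSE)
}

test_that("the radius is the nest-weighted distance percentile", {
  # one nest, distances 1..100: the 95th percentile lands on 95 exactly
  nests <- one_nest()
  pts <- make_points("n1", 1:100)
  expect_equal(estimate_radius(nests, pts, 0.95), 95)
  # all distances equal -> that distance for any percentile
  pts2 <- make_points("n1", rep(40, 17))
  for (p in c(0.05, 0.5, 0.95, 1)) {
    expect_equal(estimate_radius(nests, pts2, p), 40)
  }
  expect_error(estimate_radius(nests, pts[0, ], 0.95), "no safe")
})

test_that("the radius is invariant to duplicating a nest's points", {
  nests <- rbind(one_nest("a"), one_nest("b", x = 3000))
  pts <- rbind(make_points("a", c(10, 20, 30, 200)),
               within(make_points("b", c(50, 60, 70, 80)),
                      x <- x + 1000))
  r <- estimate_radius(nests, pts, 0.95)
  dup <- rbind(pts, within(pts[pts$nest_id == "a", ],
                           point_id <- paste0(point_id, "_dup")))
  expect_equal(estimate_radius(nests, dup, 0.95), r)
})

test_that("home-range discs clip to the expected areas", {
  # single huge field: one clipped patch whose area is the disc area
  ls <- single_field_landscape()
  hr <- build_home_range(one_nest(), ls, 188)
  expect_length(hr$patches, 1L)
  expect_lt(abs(hr$patches[[1]]$area_m2 - hr$disc_area_m2) /
              hr$disc_area_m2, 1e-6)
  # polygonized disc area at r = 188 rounds to 11.10 ha
  expect_equal(round(hr$disc_area_m2 / 1e4, 2), 11.10)
  expect_lt(abs(hr$disc_area_m2 - pi * 188^2) / (pi * 188^2), 1e-3)
  expect_lt(hr$coverage_gap_m2, 1e-6 * hr$disc_area_m2)
  # nest on the boundary of two half-plane fields: 50/50 split
  ls2 <- half_split_landscape(split = 2000)
  hr2 <- build_home_range(one_nest(), ls2, 188)
  shares <- vapply(hr2$patches, function(p) p$area_m2, 0) / hr2$disc_area_m2
  expect_length(shares, 2L)
  expect_true(all(abs(shares - 0.5) < 0.005))
})

test_that("flat-weighted availability equals plain area shares", {
  ls <- half_split_landscape(split = 2000)
  hr <- build_home_range(one_nest(), ls, 188)
  av <- weighted_surface_area(hr, profile = NULL, grid_m = 5,
                              weighting = "flat")
  expect_equal(sum(av$available$available_pct), 100, tolerance = 1e-9)
  expect_true(all(abs(av$available$available_pct - 50) < 0.5))
  # single-habitat disc: 100 under any weighting
  hr1 <- build_home_range(one_nest(), single_field_landscape(), 188)
  av1 <- weighted_surface_area(hr1, weighting = "flat")
  expect_equal(av1$available$available_pct, 100)
  expect_error(weighted_surface_area(hr, weighting = "flat", grid_m = 50),
               "coarser")
})

test_that("distance weighting follows the flight-distance profile", {
  # profile concentrated within 94 m: the inner concentric habitat takes
  # all availability, the annulus none (fine-grid integration oracle)
  ls <- concentric_landscape(inner_r = 94)
  hr <- build_home_range(one_nest(), ls, 188)
  nests <- one_nest()
  prof <- distance_profile(nests, make_points("n1", runif(200, 5, 90)))
  av <- weighted_surface_area(hr, prof, grid_m = 5)
  expect_equal(av$available$available_pct[av$available$habitat ==
                                            "winter_wheat"], 100,
               tolerance = 1e-9)
  expect_false("sugar_beet" %in%
                 av$available$habitat[av$available$available_pct > 0])
  # a profile spread over the whole disc gives both habitats weight
  prof2 <- distance_profile(nests, make_points("n1", runif(200, 5, 185)))
  av2 <- weighted_surface_area(hr, prof2, grid_m = 5)
  expect_equal(sum(av2$available$available_pct), 100, tolerance = 1e-9)
  expect_gt(min(av2$available$available_pct), 0)
})

test_that("habitat use counts in-range points with the closed-disc rule", {
  ls <- half_split_landscape(split = 2020)
  hr <- build_home_range(one_nest(), ls, 100)
  # 10 points in range: 5 west (wheat), 5 east (beet)
  pts <- rbind(make_points("n1", seq(10, 90, 20), angle = pi),
               make_points("n1", seq(30, 95, 16), angle = 0))
  hu <- habitat_use(hr, pts)
  expect_equal(hu$n_in_range, 10L)
  expect_equal(sort(hu$use$used_pct), c(50, 50))
  # a point exactly on the radius is included
  on_edge <- make_points("n1", 100, angle = pi / 2)
  hu2 <- habitat_use(hr, on_edge)
  expect_equal(hu2$n_in_range, 1L)
  # all points beyond the radius: empty use, flagged
  far <- make_points("n1", c(150, 200))
  hu3 <- habitat_use(hr, far)
  expect_true(hu3$empty)
  expect_equal(hu3$n_out_of_range, 2L)
})
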