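test_that("generated landscapes hit the configured composition and field size", {
  tr <- sim_truth(rng_seed = 7L)
  ls <- generate_landscape(tr)
  hab <- vapply(ls$patches, function(p) p$habitat_type, "")
  area <- vapply(ls$patches, function(p) p$area_m2, 0)
  fields <- !startsWith(vapply(ls$patches, function(p) p$patch_id, ""), "path")
  expect_gte(sum(fields), 200L)
  # realized area shares within 5 percentage points of the configuration
  shares <- tapply(area[fields], hab[fields], sum) / sum(area[fields])
  for (h in names(tr$habitat_proportions))
    expect_lt(abs(shares[[h]] - tr$habitat_proportions[[h]]), 0.05)
  # mean field size within 20% of the 5.1 ha target
  expect_lt(abs(mean(area[fields]) / 1e4 - tr$mean_field_ha) /
              tr$mean_field_ha, 0.2)
})

test_that("the full generator is deterministic under a fixed seed", {
  tr <- small_truth(31L, n_observed = 4L)
  s1 <- simulate_dataset(tr)
  s2 <- simulate_dataset(tr)
  for (nm in names(s1$data)) expect_identical(s1$data[[nm]], s2$data[[nm]])
  p1 <- withr::local_tempfile(fileext = ".geojson")
  p2 <- withr::local_tempfile(fileext = ".geojson")
  write_landscape(s1$landscape, p1)
  write_landscape(s2$landscape, p2)
  expect_identical(readLines(p1), readLines(p2))
  # and validates cleanly
  expect_true(validate_dataset(s1$data))
})

test_that("flight distances follow the distance kernel under uniform weights", {
  # with uniform habitat weights the landing law on the grid is
  # p(cell) ~ exp(-d/lambda); the exact distance CDF over the grid is the
  # oracle for the realized distances
  tr <- small_truth(5L, n_observed = 30L, lambda = 60,
                    flight_radius = 400, grid_m = 10)
  sim <- simulate_dataset(tr)
  fs <- filter_safe_points(sim$data$landing_points)
  d_obs <- larkscape:::point_nest_distances(
    sim$data$nests[sim$data$nests$status == "observed", ], fs$points)
  n <- length(d_obs)
  expect_gte(n, 900L)
  # exact CDF from the common cell-offset geometry
  g <- tr$grid_m; r <- tr$max_flight_radius_m
  m <- ceiling(r / g)
  off <- (seq(-m, m - 1L) + 0.5) * g
  dx <- rep(off, times = length(off)); dy <- rep(off, each = length(off))
  dcell <- sqrt(dx^2 + dy^2)
  dcell <- dcell[dcell <= r]
  p <- exp(-dcell / tr$distance_decay_lambda_m)
  o <- order(dcell)
  sup <- dcell[o]
  cdf <- cumsum(p[o]) / sum(p)
  f_emp <- ecdf(d_obs)
  ks_d <- max(abs(f_emp(sup) - cdf))
  # Kolmogorov critical value at alpha = 0.01 (conservative on a grid)
  expect_lt(ks_d, 1.628 / sqrt(n))
})

test_that("a zero-weight habitat receives no landings", {
  w0 <- stats::setNames(rep(1, 6), c("winter_wheat", "sugar_beet", "corn",
                                     "annual_flower_strip", "field_path",
                                     "other"))
  w0["sugar_beet"] <- 0
  tr <- small_truth(9L, n_observed = 6L, uniform = FALSE, base_weights = w0,
                    fvc_accessibility = FALSE, nest_pref_sdlog = 0)
  sim <- simulate_dataset(tr)
  expect_gt(nrow(sim$data$landing_points), 0L)
  expect_false("sugar_beet" %in%
                 sim$data$landing_points$habitat_type_observed)
})

test_that("a small kernel keeps flights within the study home-range scale", {
  # numeric integration over the landing grid is the oracle for the
  # within-188-m fraction at lambda_d = 35 m
  tr <- small_truth(13L, n_observed = 20L, lambda = 35,
                    flight_radius = 400, grid_m = 10)
  g <- tr$grid_m; r <- tr$max_flight_radius_m
  m <- ceiling(r / g)
  off <- (seq(-m, m - 1L) + 0.5) * g
  dx <- rep(off, times = length(off)); dy <- rep(off, each = length(off))
  dcell <- sqrt(dx^2 + dy^2)
  dcell <- dcell[dcell <= r]
  p <- exp(-dcell / 35)
  expect_gte(sum(p[dcell <= 188]) / sum(p), 0.95)   # oracle fraction
  sim <- simulate_dataset(tr)
  obs <- sim$data$nests[sim$data$nests$status == "observed", ]
  d_obs <- larkscape:::point_nest_distances(obs, sim$data$landing_points)
  expect_gte(mean(d_obs <= 188), 0.95)
})

test_that("count dispersion interpolates to the Poisson limit", {
  one_hab <- list(other = list(counts = c(Diptera = 10), mass_g = 0.03,
                               season_mult = rep(1, 6)))
  ls <- make_landscape(lapply(1:300, function(i)
    list(patch_id = sprintf("f%03d", i), habitat_type = "other:x",
         geometry = cbind(c(i, i + 1, i + 1, i) * 10,
                          c(0, 0, 10, 10)))), 2018L)
  tr_pois <- sim_truth(rng_seed = 3L, arthropod_means = one_hab,
                       dispersion = 1e9, missing_covariate_prob = 0)
  cv <- simulate_covariates(tr_pois, ls)
  counts <- cv$arthropod_samples$count_Diptera
  expect_equal(length(counts), 300L)
  expect_lt(abs(var(counts) / mean(counts) - 1), 0.35)
  # small size parameter -> clearly overdispersed
  tr_nb <- sim_truth(rng_seed = 3L, arthropod_means = one_hab,
                     dispersion = 0.5, missing_covariate_prob = 0)
  cnb <- simulate_covariates(tr_nb, ls)$arthropod_samples$count_Diptera
  expect_gt(var(cnb) / mean(cnb), 3)
})

test_that("a single-order community yields Shannon H of zero everywhere", {
  one_hab <- list(other = list(counts = c(Diptera = 25), mass_g = 0.03,
                               season_mult = rep(1, 6)))
  tr <- small_truth(21L, n_observed = 2L, arthropod_means = one_hab,
                    missing_covariate_prob = 0)
  sim <- simulate_dataset(tr)
  h <- apply(sim$data$arthropod_samples, 1, function(row) {
    cnt <- as.numeric(row[grep("^count_", names(row))])
    if (sum(cnt) == 0) NA_real_ else shannon_index(cnt)
  })
  expect_true(all(h[!is.na(h)] == 0))
})

test_that("observer cover estimates are 10%-step values in range", {
  tr <- small_truth(17L, n_observed = 3L)
  sim <- simulate_dataset(tr)
  veg <- sim$data$vegetation
  est <- c(veg$est1, veg$est2, veg$est3)
  expect_true(all(est %% 10 == 0))
  expect_true(all(est >= 0 & est <= 100))
})
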