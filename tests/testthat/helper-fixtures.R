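# Fixtures built in code: tiny landscapes, consistent observation tables,
# and a scaled-down simulation truth for pipeline tests.

# One huge square field of a single habitat.
single_field_landscape <- function(habitat = "winter_wheat", size = 4000) {
  make_landscape(list(list(patch_id = "f1", habitat_type = habitat,
                           geometry = cbind(c(0, size, size, 0),
                                            c(0, 0, size, size)))),
                 year = 2018L)
}

# Two half-plane fields split at x = split.
half_split_landscape <- function(split = 2000, size = 4000,
                                 habitats = c("winter_wheat", "sugar_beet")) {
  make_landscape(list(
    list(patch_id = "west", habitat_type = habitats[1],
         geometry = cbind(c(0, split, split, 0), c(0, 0, size, size))),
    list(patch_id = "east", habitat_type = habitats[2],
         geometry = cbind(c(split, size, size, split), c(0, 0, size, size)))),
    year = 2018L)
}

# A background field with an inner near-disc of another habitat drawn on
# top (later patch wins in point location).
concentric_landscape <- function(center = c(2000, 2000), inner_r = 94,
                                 size = 4000) {
  make_landscape(list(
    list(patch_id = "outer", habitat_type = "sugar_beet",
         geometry = cbind(c(0, size, size, 0), c(0, 0, size, size))),
    list(patch_id = "inner", habitat_type = "winter_wheat",
         geometry = disc_polygon(center, inner_r / cos(pi / 128), 128L))),
    year = 2018L)
}

# Minimal consistent observation tables around one or more nests.
tiny_tables <- function(n_nests = 2L, points_per_nest = 5L) {
  nests <- data.frame(
    nest_id = sprintf("n%02d", seq_len(n_nests)),
    x = 1000 + 100 * seq_len(n_nests), y = 1000,
    year = 2018L, hatch_date = as.Date("2018-05-10"),
    brood_size = 3L, fate = "success", radio_tagged = FALSE,
    status = "observed", mapped = TRUE, sunset_excluded = FALSE,
    brood_unclear = FALSE, n_chicks = 3L, n_starved = 0L,
    stringsAsFactors = FALSE)
  sessions <- data.frame(
    session_id = paste0(nests$nest_id, "_s01"), nest_id = nests$nest_id,
    date = as.Date("2018-05-15"), start_time_min = 600,
    duration_min = 60, chick_age_days = 5L, brood_size = 3L,
    temperature_C = 18, wind_kmh = 8, ended_before_sunset = TRUE,
    stringsAsFactors = FALSE)
  pts <- do.call(rbind, lapply(seq_len(n_nests), function(i) data.frame(
    point_id = sprintf("%s_p%02d", sessions$session_id[i],
                       seq_len(points_per_nest)),
    session_id = sessions$session_id[i], nest_id = nests$nest_id[i],
    x = nests$x[i] + 10 * seq_len(points_per_nest), y = 1000,
    safe = TRUE, habitat_type_observed = "winter_wheat",
    stringsAsFactors = FALSE)))
  arth <- data.frame(sample_id = "a_f1", patch_id = "f1",
                     date = as.Date("2018-05-20"),
                     device_diameter_m = 0.14, n_touchdowns = 20L,
                     dry_mass_g = 0.05, count_Diptera = 10L,
                     count_Coleoptera = 5L, stringsAsFactors = FALSE)
  veg <- data.frame(record_id = "v_f1", patch_id = "f1",
                    date = as.Date("2018-05-20"), est1 = 40, est2 = 50,
                    est3 = 60, low_vegetation = FALSE,
                    is_field_path = FALSE, stringsAsFactors = FALSE)
  list(nests = nests, sessions = sessions, landing_points = pts,
       arthropod_samples = arth, vegetation = veg)
}

# Scaled-down simulation truth for pipeline tests: fewer nests, smaller
# extent and coarser landing grid than the full study defaults.
small_truth <- function(seed, n_observed = 10L, n_mapped = n_observed,
                        lambda = 60, uniform = TRUE, extent = 1500,
                        flight_radius = 250, grid_m = 10, ...) {
  args <- list(rng_seed = seed,
               distance_decay_lambda_m = lambda,
               n_nests_found = n_observed, n_inactive = 0L,
               n_unobservable = 0L, n_chicks_too_old = 0L,
               n_mapped = n_mapped, n_radio_tagged = min(2L, n_mapped),
               extent_m = extent, max_flight_radius_m = flight_radius,
               grid_m = grid_m, ...)
  if (uniform) {
    hab <- c("winter_wheat", "sugar_beet", "corn", "annual_flower_strip",
             "field_path", "other")
    args$base_weights <- stats::setNames(rep(1, 6), hab)
    args$fvc_accessibility <- FALSE
    args$nest_pref_sdlog <- 0
  }
  do.call(sim_truth, args)
}

# Independent one-sample Hotelling route to Wilk's lambda:
# lambda = 1 / (1 + T^2/(n-1)),  T^2 = n * dbar' S^{-1} dbar.
wilks_oracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  dbar <- colMeans(d)
  S <- stats::cov(d)
  t2 <- n * as.numeric(t(dbar) %*% solve(S) %*% dbar)
  1 / (1 + t2 / (n - 1))
}

# Construct an RSF point table directly: selection driven by distance
# (logit decreasing in d) with covariates of known relevance.
synth_rsf_points <- function(seed, n_nests = 6L, n_pres = 40L,
                             n_abs = 120L, distance_effect = TRUE) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_nests)) {
    nid <- sprintf("n%02d", i)
    d_abs <- 250 * sqrt(runif(n_abs))            # uniform over a disc
    d_pre <- if (distance_effect) rgamma(n_pres, 2, rate = 1 / 45)
             else 250 * sqrt(runif(n_pres))
    mk <- function(d, kind) data.frame(
      nest_id = nid, kind = kind, distance_m = pmin(d, 250),
      fvc_pct = round(runif(length(d), 0, 100), 1),
      biomass_gm2 = rlnorm(length(d), -2, 0.6),
      shannon_H = runif(length(d), 0, 2), stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- mk(d_pre, "presence")
    rows[[length(rows) + 1L]] <- mk(d_abs, "pseudo_absence")
  }
  assign_weights(do.call(rbind, rows))
}

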