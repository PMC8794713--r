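# Synthetic study generator: a crop mosaic, nests, central-place foraging
# flights with an exponential distance kernel times habitat attractiveness,
# and per-patch arthropod/vegetation covariates -- all with known ground
# truth so every pipeline stage can be tested against it.
#
# Each generator draws from its own seeded stream (rng_seed + fixed offset)
# so the full dataset is reproducible and individual generators are
# deterministic in isolation.

#' Ground-truth parameters for the synthetic study
#'
#' Defaults emulate the observed structure of a two-year Central European
#' farmland study: a ~3.4 km square mosaic with ~5 ha fields dominated by
#' winter wheat and sugar beet plus thin field-path strips; 96 found nests
#' of which 51 are observable (42 with mapped surroundings, 12 radio-tagged);
#' foraging flights following \eqn{\exp(-d/\lambda_d)} with
#' \eqn{\lambda_d = 40} m, modulated by habitat attractiveness and by an
#' accessibility penalty that declines with vegetation cover around 70%;
#' feeding visits arriving with ~5.3 min mean gaps (about 11.3 visits/h);
#' negative-binomial arthropod counts by insect order and logistic crop
#' growth.  See the methods vignette for the rationale of every default.
#'
#' @param rng_seed Integer seed governing all generator streams.
#' @param distance_decay_lambda_m Mean of the exponential flight-distance
#'   kernel (m).
#' @param base_weights Named habitat attractiveness multipliers; the name
#'   \code{other} covers all \code{other:*} habitats.
#' @param seasonal_factor Named fold-change of attractiveness from day 1 to
#'   day 100 of the season (1 = constant).
#' @param fvc_accessibility If TRUE, attractiveness is multiplied by a
#'   declining logistic in true vegetation cover (midpoint 70%).
#' @param arthropod_means Per-habitat list with \code{counts} (named mean
#'   counts per insect order at mid-season), \code{mass_g} (mean dry mass
#'   per sample) and \code{season_mult} (length-6 half-month multipliers).
#' @param dispersion Negative-binomial size parameter for counts.
#' @param veg_growth Per-habitat logistic growth parameters
#'   (\code{asym} percent, \code{midpoint_day}, \code{rate} per day).
#' @param habitat_proportions Named field-type probabilities for the mosaic.
#' @param mean_field_ha Target mean arable field size (ha).
#' @param extent_m Side length of the square landscape (m).
#' @param path_width_m Width of field-path strips between field columns (m).
#' @param n_nests_found,n_inactive,n_unobservable,n_chicks_too_old Nest
#'   accounting; observed nests are the remainder.
#' @param n_mapped Observed nests with mapped surroundings (covariate data).
#' @param n_radio_tagged Observed nests with a radio-tagged parent.
#' @param ambiguous_prob Probability a landing point is ambiguous (unsafe).
#' @param starvation_rate Fraction of chicks lost to starvation.
#' @param session_gap_mean_min Mean gap between feeding visits (min).  A
#'   session ends at the 10th visit, so the observed frequency estimate
#'   n/duration carries a k/(k-1) stopping bias; the default encodes a
#'   target mean observed frequency of ~11.3 visits/h.
#' @param nest_pref_sdlog SD (log scale) of per-nest, per-patch
#'   foraging-site preference multipliers: each nest scales the
#'   attractiveness of each individual patch by an independent lognormal
#'   factor, emulating site fidelity (birds repeatedly commuting to
#'   particular fields) and the between-nest variation that nest random
#'   effects pick up in the field.  0 disables heterogeneity.
#' @param max_flight_radius_m Support radius of the landing grid (m).
#' @param grid_m Landing-grid cell size (m).
#' @param missing_covariate_prob Probability a patch goes unsampled.
#' @param brood_probs Probabilities of brood sizes 1..5.
#' @return A list of class \code{sim_truth}.
#' @export
sim_truth <- function(rng_seed = 1L,
                      distance_decay_lambda_m = 40,
                      base_weights = c(winter_wheat = 0.85, sugar_beet = 0.9,
                                       corn = 1, annual_flower_strip = 2,
                                       field_path = 2, other = 0.6),
                      seasonal_factor = c(winter_wheat = 1, sugar_beet = 1,
                                          corn = 1, annual_flower_strip = 1,
                                          field_path = 1, other = 1),
                      fvc_accessibility = TRUE,
                      arthropod_means = default_arthropod_means(),
                      dispersion = 1,
                      veg_growth = default_veg_growth(),
                      habitat_proportions = c(winter_wheat = 0.35,
                                              sugar_beet = 0.21, corn = 0.10,
                                              annual_flower_strip = 0.05,
                                              "other:winter_barley" = 0.08,
                                              "other:winter_rape" = 0.07,
                                              "other:fallow" = 0.06,
                                              "other:grassland" = 0.08),
                      mean_field_ha = 5.1,
                      extent_m = 3400,
                      path_width_m = 4,
                      n_nests_found = 96L, n_inactive = 22L,
                      n_unobservable = 15L, n_chicks_too_old = 8L,
                      n_mapped = 42L, n_radio_tagged = 12L,
                      ambiguous_prob = 53 / 2243,
                      starvation_rate = 3 / 178,
                      session_gap_mean_min = 5.9,
                      nest_pref_sdlog = 1,
                      max_flight_radius_m = 500,
                      grid_m = 5,
                      missing_covariate_prob = 0.03,
                      brood_probs = c(0.03, 0.12, 0.33, 0.37, 0.15)) {
  stopifnot(distance_decay_lambda_m > 0, all(base_weights >= 0),
            dispersion > 0, abs(sum(habitat_proportions) - 1) < 1e-8,
            all(vapply(veg_growth, function(v) v$asym, 0) <= 100))
  structure(as.list(environment()), class = "sim_truth")
}

#' @rdname sim_truth
#' @export
default_arthropod_means <- function() {
  hm <- function(counts, mass, mult = c(0.6, 0.8, 1.0, 1.2, 1.3, 1.4))
    list(counts = counts, mass_g = mass, season_mult = mult)
  list(
    winter_wheat = hm(c(Diptera = 14, Hemiptera = 10, Coleoptera = 6,
                        Hymenoptera = 3, Araneae = 2), 0.035),
    sugar_beet = hm(c(Diptera = 8, Hemiptera = 2, Coleoptera = 3,
                      Hymenoptera = 1, Araneae = 1), 0.012),
    corn = hm(c(Diptera = 9, Hemiptera = 4, Coleoptera = 4,
                Hymenoptera = 2, Araneae = 1), 0.030),
    annual_flower_strip = hm(c(Diptera = 16, Hemiptera = 12, Coleoptera = 8,
                               Hymenoptera = 6, Lepidoptera = 2, Araneae = 3),
                             0.045),
    field_path = hm(c(Diptera = 18, Hemiptera = 14, Coleoptera = 9,
                      Hymenoptera = 7, Orthoptera = 3, Araneae = 4), 0.070),
    other = hm(c(Diptera = 10, Hemiptera = 6, Coleoptera = 4,
                 Hymenoptera = 2, Araneae = 2), 0.030))
}

#' @rdname sim_truth
#' @export
default_veg_growth <- function() {
  vg <- function(asym, mid, rate) list(asym = asym, midpoint_day = mid, rate = rate)
  list(winter_wheat = vg(92, -5, 0.10),       # already dense at season start
       sugar_beet = vg(85, 45, 0.09),
       corn = vg(80, 60, 0.10),
       annual_flower_strip = vg(88, 30, 0.08),
       field_path = vg(0, 50, 0.1),           # bare by convention
       other = vg(80, 20, 0.07))
}

# Parameter lookup for a (possibly other:*) habitat label.
truth_param <- function(map, habitat) {
  key <- if (habitat %in% names(map)) habitat else "other"
  map[[key]]
}

#' True fractional vegetation cover of a habitat on a season day
#'
#' The noiseless logistic growth curve the generator perturbs and rounds to
#' produce observer estimates.
#'
#' @param truth A [sim_truth()].
#' @param habitat Habitat label.
#' @param day Day of season (numeric vector).
#' @return FVC percent in [0, 100].
#' @export
true_fvc <- function(truth, habitat, day) {
  g <- truth_param(truth$veg_growth, habitat)
  g$asym / (1 + exp(-g$rate * (day - g$midpoint_day)))
}

# Attractiveness of a habitat on a (scalar) season day, excluding the
# distance kernel.  Vectorized over habitat via unique-label lookup.
habitat_attractiveness <- function(truth, habitat, day) {
  stopifnot(length(day) == 1L)
  bw <- as.list(truth$base_weights)
  sf <- as.list(truth$seasonal_factor)
  uh <- unique(habitat)
  wu <- vapply(uh, function(h) {
    w <- truth_param(bw, h) * truth_param(sf, h)^((day - 1) / 100)
    if (isTRUE(truth$fvc_accessibility)) {
      fvc <- true_fvc(truth, h, day)
      w <- w * (0.3 + 0.7 / (1 + exp((fvc - 70) / 6)))
    }
    w
  }, 0)
  unname(wu[match(habitat, uh)])
}

# --- landscape ---------------------------------------------------------

#' Generate a crop-mosaic landscape
#'
#' Columns of rectangular fields with jittered widths and heights sized to
#' the target mean field area, separated by thin field-path strips; habitat
#' types drawn from the configured proportions.  Deterministic given the
#' seed.
#'
#' @param truth A [sim_truth()].
#' @param year Study year attached to the patches.
#' @return A \code{landscape}.
#' @export
generate_landscape <- function(truth, year = 2018L) {
  set.seed(truth$rng_seed)
  ext <- truth$extent_m
  # widths x heights averaging ~ mean_field_ha
  side <- sqrt(truth$mean_field_ha * 1e4)
  patches <- list()
  x0 <- 0
  col <- 0L
  while (x0 < ext) {
    col <- col + 1L
    w <- stats::runif(1, 0.75 * side, 1.29 * side)
    w <- min(w, ext - x0)
    y0 <- 0
    row <- 0L
    while (y0 < ext) {
      row <- row + 1L
      h <- stats::runif(1, 0.70 * side, 1.22 * side)
      h <- min(h, ext - y0)
      if (w > 1 && h > 1) {
        hab <- sample(names(truth$habitat_proportions), 1L,
                      prob = truth$habitat_proportions)
        patches[[length(patches) + 1L]] <- list(
          patch_id = sprintf("f%02d_%02d", col, row),
          habitat_type = hab,
          geometry = cbind(c(x0, x0 + w, x0 + w, x0),
                           c(y0, y0, y0 + h, y0 + h)))
      }
      y0 <- y0 + h
    }
    x0 <- x0 + w
    # field-path strip after each column (drawn on top of nothing: strip
    # occupies its own band)
    if (x0 + truth$path_width_m < ext) {
      patches[[length(patches) + 1L]] <- list(
        patch_id = sprintf("path%02d", col),
        habitat_type = "field_path",
        geometry = cbind(c(x0, x0 + truth$path_width_m,
                           x0 + truth$path_width_m, x0),
                         c(0, 0, ext, ext)))
      x0 <- x0 + truth$path_width_m
    }
  }
  make_landscape(patches, year)
}

# --- nests -------------------------------------------------------------

#' Generate the nest table
#'
#' 96 found nests with the study's accounting (inactive / unobservable /
#' chicks-too-old / observed), hatch dates spanning late April to mid July,
#' brood sizes, mapping and radio-tagging flags, and chick starvation
#' counts at the configured rate.
#'
#' @param truth A [sim_truth()].
#' @param landscape The landscape the nests must lie in.
#' @param years Study years to assign (split evenly).
#' @return Nest data.frame.
#' @export
generate_nests <- function(truth, landscape, years = c(2018L, 2019L)) {
  set.seed(truth$rng_seed + 1L)
  n <- truth$n_nests_found
  margin <- truth$max_flight_radius_m + 50
  ext <- truth$extent_m
  x <- stats::runif(n, margin, ext - margin)
  y <- stats::runif(n, margin, ext - margin)
  status <- sample(rep(c("inactive_before_observation", "unobservable",
                         "chicks_too_old", "observed"),
                       c(truth$n_inactive, truth$n_unobservable,
                         truth$n_chicks_too_old,
                         n - truth$n_inactive - truth$n_unobservable -
                           truth$n_chicks_too_old)))
  # hatch dates: month pattern of the observed study population
  mon <- sample(c(4L, 5L, 6L, 7L), n, replace = TRUE,
                prob = c(3, 17, 21, 10) / 51)
  day <- ifelse(mon == 4L, sample(25:30, n, replace = TRUE),
         ifelse(mon == 7L, sample(1:15, n, replace = TRUE),
                sample(1:28, n, replace = TRUE)))
  yr <- sample(rep(years, length.out = n))
  hatch <- as.Date(sprintf("%d-%02d-%02d", yr, mon, day))
  brood <- sample(1:5, n, replace = TRUE, prob = truth$brood_probs)
  obs <- which(status == "observed")
  mapped <- rep(FALSE, n); mapped[sample(obs, truth$n_mapped)] <- TRUE
  radio <- rep(FALSE, n); radio[sample(obs, truth$n_radio_tagged)] <- TRUE
  special <- sample(obs, 2L)   # one sunset-excluded, one unclear-brood nest
  n_chicks <- brood
  n_starved <- integer(n)
  tot <- sum(n_chicks[obs])
  starve <- sample(obs, max(1L, round(truth$starvation_rate * tot)),
                   prob = n_chicks[obs], replace = FALSE)
  n_starved[starve] <- 1L
  data.frame(nest_id = sprintf("n%03d", seq_len(n)),
             x = x, y = y, year = yr, hatch_date = hatch,
             brood_size = brood, fate = sample(c("success", "predated"), n,
                                               replace = TRUE, prob = c(.7, .3)),
             radio_tagged = radio, status = status, mapped = mapped,
             sunset_excluded = seq_len(n) == special[1],
             brood_unclear = seq_len(n) == special[2],
             n_chicks = n_chicks, n_starved = n_starved,
             stringsAsFactors = FALSE)
}

# --- flights -----------------------------------------------------------

# Landing grid around a nest: cell centers within max radius, with habitat.
nest_landing_grid <- function(truth, landscape, nx, ny) {
  g <- truth$grid_m
  r <- truth$max_flight_radius_m
  m <- ceiling(r / g)
  off <- (seq(-m, m - 1L) + 0.5) * g        # symmetric about the nest
  gx <- rep(nx + off, times = length(off))
  gy <- rep(ny + off, each = length(off))
  d <- sqrt((gx - nx)^2 + (gy - ny)^2)
  keep <- d <= r
  gx <- gx[keep]; gy <- gy[keep]; d <- d[keep]
  # restrict the landscape to patches whose bbox meets the grid window
  near <- Filter(function(p)
    p$bbox[2] >= nx - r && p$bbox[1] <= nx + r &&
      p$bbox[4] >= ny - r && p$bbox[3] <= ny + r, landscape$patches)
  loc <- locate_points(structure(list(year = landscape$year, patches = near),
                                 class = "landscape"), gx, gy)
  list(x = gx, y = gy, d = d, habitat = loc$habitat_type,
       patch_id = loc$patch_id)
}

#' Simulate observation sessions and foraging flights
#'
#' For each observed nest, sessions on consecutive chick days; within a
#' session, feeding visits arrive with exponential gaps until 10 flights or
#' 90 min.  Landing cells are drawn on a fine grid with probability
#' proportional to \eqn{\exp(-d/\lambda_d)} times the day-specific habitat
#' attractiveness.  A small fraction of landing points is flagged ambiguous
#' (\code{safe = FALSE}).
#'
#' @param truth A [sim_truth()].
#' @param landscape The landscape.
#' @param nests Nest table from [generate_nests()].
#' @param config A [study_config()] (calendar convention).
#' @return List with \code{sessions} and \code{landing_points} data.frames.
#' @export
simulate_flights <- function(truth, landscape, nests, config = study_config()) {
  set.seed(truth$rng_seed + 2L)
  margin <- c(min(vapply(landscape$patches, function(p) p$bbox[1], 0)),
              max(vapply(landscape$patches, function(p) p$bbox[2], 0)),
              min(vapply(landscape$patches, function(p) p$bbox[3], 0)),
              max(vapply(landscape$patches, function(p) p$bbox[4], 0)))
  sess <- list(); pts <- list()
  for (i in which(nests$status == "observed")) {
    nst <- nests[i, ]
    if (nst$x < margin[1] || nst$x > margin[2] ||
        nst$y < margin[3] || nst$y > margin[4])
      stop("nest ", nst$nest_id, " lies outside the landscape")
    grid <- nest_landing_grid(truth, landscape, nst$x, nst$y)
    kern <- exp(-grid$d / truth$distance_decay_lambda_m)
    known <- !is.na(grid$habitat)
    # per-nest patch preference multipliers (site fidelity heterogeneity)
    up <- unique(grid$patch_id[known])
    pref <- stats::setNames(stats::rlnorm(length(up), 0,
                                          truth$nest_pref_sdlog), up)
    n_sessions <- 3L + stats::rpois(1L, 1.3)
    age0 <- sample(1:2, 1L)
    for (s in seq_len(n_sessions)) {
      age <- age0 + s - 1L
      if (age > 9L) break
      date <- nst$hatch_date + age
      dos <- suppressWarnings(day_of_season(date, config))
      attr_w <- habitat_attractiveness(truth, grid$habitat[known], dos)
      w <- numeric(length(kern))
      w[known] <- kern[known] * attr_w * pref[grid$patch_id[known]]
      if (!any(w > 0)) stop("nest ", nst$nest_id, ": no attainable landing cell")
      gaps <- stats::rexp(10L, rate = 1 / truth$session_gap_mean_min)
      tt <- cumsum(gaps)
      nfl <- sum(tt <= 90)
      dur <- if (nfl >= 10L) tt[10L] else 90
      nfl <- max(1L, min(10L, nfl))
      sid <- sprintf("%s_s%02d", nst$nest_id, s)
      sess[[length(sess) + 1L]] <- data.frame(
        session_id = sid, nest_id = nst$nest_id, date = date,
        start_time_min = round(stats::runif(1, 300, 1200)),
        duration_min = round(dur, 1),
        chick_age_days = age, brood_size = nst$brood_size,
        temperature_C = round(stats::rnorm(1, 14 + 0.08 * dos, 3), 1),
        wind_kmh = round(stats::rgamma(1, shape = 2.5, scale = 4), 1),
        ended_before_sunset = !isTRUE(nst$sunset_excluded),
        stringsAsFactors = FALSE)
      cell <- sample.int(length(w), nfl, replace = TRUE, prob = w)
      pts[[length(pts) + 1L]] <- data.frame(
        point_id = sprintf("%s_p%02d", sid, seq_len(nfl)),
        session_id = sid, nest_id = nst$nest_id,
        x = grid$x[cell], y = grid$y[cell],
        safe = stats::runif(nfl) >= truth$ambiguous_prob,
        habitat_type_observed = grid$habitat[cell],
        stringsAsFactors = FALSE)
    }
  }
  list(sessions = do.call(rbind, sess), landing_points = do.call(rbind, pts))
}

# --- covariates --------------------------------------------------------

half_month_index <- function(day_of_season) {
  # six half-months from May to July (day 1 = Apr 25; May 7 ~ day 13)
  pmin(6L, pmax(1L, 1L + (as.integer(day_of_season) - 1L) %/% 16L))
}

#' Simulate arthropod samples and vegetation records
#'
#' One vacuum sample (negative-binomial counts per insect order, lognormal
#' dry mass) and one vegetation record (three observer estimates of the
#' logistic growth curve, rounded to 10% steps) per patch; a small fraction
#' of patches is left unsampled to exercise the imputation path.
#'
#' @param truth A [sim_truth()].
#' @param landscape The landscape.
#' @param config A [study_config()].
#' @return List with \code{arthropod_samples} and \code{vegetation}.
#' @export
simulate_covariates <- function(truth, landscape, config = study_config()) {
  set.seed(truth$rng_seed + 3L)
  orders <- sort(unique(unlist(lapply(truth$arthropod_means,
                                      function(m) names(m$counts)))))
  samp <- list(); veg <- list()
  for (p in landscape$patches) {
    if (stats::runif(1) < truth$missing_covariate_prob) next
    dos <- sample(10:70, 1L)
    date <- as.Date(paste0(landscape$year, "-", config$day_one)) + dos - 1L
    am <- truth_param(truth$arthropod_means, p$habitat_type)
    mult <- am$season_mult[half_month_index(dos)]
    cnt <- stats::setNames(integer(length(orders)), orders)
    cnt[names(am$counts)] <- stats::rnbinom(length(am$counts),
                                            mu = am$counts * mult,
                                            size = truth$dispersion)
    sdlog <- 0.5
    mass <- stats::rlnorm(1, log(am$mass_g * mult) - sdlog^2 / 2, sdlog)
    row <- data.frame(sample_id = paste0("a_", p$patch_id),
                      patch_id = p$patch_id, date = date,
                      device_diameter_m = 0.14, n_touchdowns = 20L,
                      dry_mass_g = round(mass, 5), stringsAsFactors = FALSE)
    for (o in orders) row[[paste0("count_", o)]] <- unname(cnt[o])
    samp[[length(samp) + 1L]] <- row
    fvc0 <- true_fvc(truth, p$habitat_type, dos)
    est <- pmin(100, pmax(0, round((fvc0 + stats::runif(3, -10, 10)) / 10) * 10))
    veg[[length(veg) + 1L]] <- data.frame(
      record_id = paste0("v_", p$patch_id), patch_id = p$patch_id,
      date = date, est1 = est[1], est2 = est[2], est3 = est[3],
      low_vegetation = FALSE,
      is_field_path = p$habitat_type == "field_path",
      stringsAsFactors = FALSE)
  }
  list(arthropod_samples = do.call(rbind, samp),
       vegetation = do.call(rbind, veg))
}

#' Simulate a complete study dataset
#'
#' Runs all generators and returns the tables [read_tables()] reads, the
#' landscape, and the generating truth.
#'
#' @param truth A [sim_truth()].
#' @param config A [study_config()].
#' @param year Landscape/mosaic year (nests span both study years; the
#'   mosaic is reused, which the analyses treat per nest anyway).
#' @return List with \code{landscape}, \code{data} (table list) and
#'   \code{truth}.
#' @export
simulate_dataset <- function(truth = sim_truth(), config = study_config(),
                             year = 2018L) {
  landscape <- generate_landscape(truth, year)
  nests <- generate_nests(truth, landscape)
  fl <- simulate_flights(truth, landscape, nests, config)
  cv <- simulate_covariates(truth, landscape, config)
  data <- list(nests = nests, sessions = fl$sessions,
               landing_points = fl$landing_points,
               arthropod_samples = cv$arthropod_samples,
               vegetation = cv$vegetation)
  validate_dataset(data)
  list(landscape = landscape, data = data, truth = truth)
}

#' Write the generating truth to JSON
#'
#' @param truth A [sim_truth()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
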