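# Stage drivers: thin orchestration over the module functions so the
# analysis scripts, the test-suite and the acceptance script run the same
# code paths.

#' Home-range stage
#'
#' Safe-point filtering, the shared radius, per-nest home ranges, the
#' pooled distance profile, and per-nest availability and use tables.
#'
#' @param landscape A \code{landscape}.
#' @param data Table list from [read_tables()] or [simulate_dataset()].
#' @param config A [study_config()].
#' @param grid_m Availability grid (m).
#' @param weighting "distance" or "flat" availability weighting.
#' @return List of class \code{hr_stage}: radius_m, home_ranges,
#'   availability, use, use_points (point-level table with mapped habitat
#'   and session date), profile, safe summary.
#' @export
pipeline_home_ranges <- function(landscape, data, config = study_config(),
                                 grid_m = 5, weighting = "distance") {
  fs <- filter_safe_points(data$landing_points)
  obs <- data$nests[data$nests$status == "observed", , drop = FALSE]
  radius <- estimate_radius(obs, fs$points, config$home_range_percentile)
  profile <- distance_profile(obs, fs$points)
  hrs <- list(); avail <- list(); use <- list(); upts <- list()
  for (i in seq_len(nrow(obs))) {
    hr <- build_home_range(obs[i, ], landscape, radius)
    hrs[[hr$nest_id]] <- hr
    av <- weighted_surface_area(hr, profile, grid_m, weighting)
    avail[[hr$nest_id]] <- cbind(nest_id = hr$nest_id, av$available,
                                 stringsAsFactors = FALSE)
    hu <- habitat_use(hr, fs$points)
    if (!hu$empty) {
      use[[hr$nest_id]] <- cbind(nest_id = hr$nest_id, hu$use,
                                 stringsAsFactors = FALSE)
      pts <- fs$points[fs$points$nest_id == hr$nest_id, , drop = FALSE]
      d <- sqrt((pts$x - hr$center[1])^2 + (pts$y - hr$center[2])^2)
      pin <- pts[d <= radius + 1e-9, , drop = FALSE]
      loc <- locate_points(structure(list(year = NA_integer_,
                                          patches = hr$patches),
                                     class = "landscape"), pin$x, pin$y)
      upts[[hr$nest_id]] <- data.frame(
        point_id = pin$point_id, nest_id = pin$nest_id,
        session_id = pin$session_id, x = pin$x, y = pin$y,
        patch_id = loc$patch_id, habitat = loc$habitat_type,
        distance_m = d[d <= radius + 1e-9],
        date = data$sessions$date[match(pin$session_id,
                                        data$sessions$session_id)],
        stringsAsFactors = FALSE)
    }
  }
  structure(list(radius_m = radius, home_ranges = hrs,
                 availability = do.call(rbind, avail),
                 use = do.call(rbind, use),
                 use_points = do.call(rbind, upts),
                 profile = profile, safe_summary = fs$summary),
            class = "hr_stage")
}

#' Resource-selection stage
#'
#' Builds the weighted presence/pseudo-absence point set for the mapped
#' nests (covariates joined per home-range patch; presences with missing
#' covariates dropped and counted; pseudo-absences drawn only in
#' covariate-complete patches), fits the additive model, and computes
#' selection curves and permutation importance.
#'
#' @param hr An \code{hr_stage}.
#' @param data Table list.
#' @param config A [study_config()].
#' @param n_perm Permutation replicates for importance.
#' @param k Basis dimension per smooth.
#' @return List of class \code{rsf_stage}: points, fit, curves,
#'   importance.
#' @export
pipeline_rsf <- function(hr, data, config = study_config(), n_perm = 100L,
                         k = 10) {
  mapped <- data$nests$nest_id[data$nests$status == "observed" &
                                 data$nests$mapped]
  recs <- list()
  for (nid in intersect(mapped, names(hr$home_ranges))) {
    hrange <- hr$home_ranges[[nid]]
    cov <- assemble_covariates(hrange, data$arthropod_samples,
                               data$vegetation)
    ok <- stats::complete.cases(cov[, c("fvc_pct", "biomass_gm2",
                                        "shannon_H")])
    valid_ids <- cov$patch_id[ok]
    up <- hr$use_points[hr$use_points$nest_id == nid, , drop = FALSE]
    if (!nrow(up)) next
    ci <- match(up$patch_id, cov$patch_id)
    pres <- data.frame(point_id = up$point_id, nest_id = nid,
                       kind = "presence", distance_m = up$distance_m,
                       fvc_pct = cov$fvc_pct[ci],
                       biomass_gm2 = cov$biomass_gm2[ci],
                       shannon_H = cov$shannon_H[ci],
                       stringsAsFactors = FALSE)
    pa <- generate_pseudo_absences(hrange,
                                   config$pseudo_absences_per_home_range,
                                   seed = config$rng_seed +
                                     match(nid, mapped),
                                   valid_patch_ids = valid_ids)
    cj <- match(pa$patch_id, cov$patch_id)
    abs_ <- data.frame(point_id = pa$point_id, nest_id = nid,
                       kind = "pseudo_absence", distance_m = pa$distance_m,
                       fvc_pct = cov$fvc_pct[cj],
                       biomass_gm2 = cov$biomass_gm2[cj],
                       shannon_H = cov$shannon_H[cj],
                       stringsAsFactors = FALSE)
    recs[[nid]] <- rbind(pres, abs_)
  }
  pts <- assign_weights(do.call(rbind, recs))
  fit <- fit_rsf(pts, k = k)
  curves <- do.call(rbind, lapply(fit$predictors, function(p)
    classify_selection(fit, p)))
  imp <- permutation_importance(fit, n_reps = n_perm,
                                seed = config$rng_seed)
  structure(list(points = pts, fit = fit, curves = curves,
                 importance = imp),
            class = "rsf_stage")
}

#' Compositional stage
#'
#' @param hr An \code{hr_stage}.
#' @param config A [study_config()].
#' @return A \code{compositional_result}.
#' @export
pipeline_compositional <- function(hr, config = study_config()) {
  compositional_analysis(hr$availability, hr$use, config)
}

#' Seasonal-use stage
#'
#' One mixed logistic model per selected category except "other", with its
#' prediction curve classified against availability.
#'
#' @param hr An \code{hr_stage}.
#' @param data Table list.
#' @param config A [study_config()].
#' @param habitats Focal habitats (default: the selected categories).
#' @return Named list of per-habitat lists (fit, classification).
#' @export
pipeline_seasonal <- function(hr, data, config = study_config(),
                              habitats = NULL) {
  if (is.null(habitats)) {
    cats <- select_categories(hr$availability,
                              config$frequent_habitat_fraction)
    habitats <- setdiff(cats, "other")
  }
  out <- list()
  for (h in habitats) {
    des <- build_seasonal_design(h, hr$use_points, hr$availability,
                                 data$nests, config)
    fit <- fit_seasonal_model(des)
    out[[h]] <- list(fit = fit,
                     classification = classify_against_availability(fit))
  }
  out
}

#' Foraging-parameter stage
#'
#' @param data Table list.
#' @param config A [study_config()].
#' @return List of class \code{foraging_stage}: frequency records, flight
#'   distances, MCP95 table, trend models, and headline means.
#' @export
pipeline_foraging <- function(data, config = study_config()) {
  obs <- data$nests[data$nests$status == "observed", , drop = FALSE]
  sess <- data$sessions
  freq <- feeding_frequencies(sess, data$landing_points, obs)
  dist <- flight_distances(obs, data$landing_points)
  mcp <- mcp95_by_nest(obs, data$landing_points, config)
  trends <- fit_trend_models(freq, dist, mcp, sess, obs, config)
  structure(list(frequencies = freq, distances = dist, mcp = mcp,
                 trends = trends,
                 means = list(
                   per_h = mean(freq$records$per_h),
                   per_h_chick = mean(freq$records$per_h_chick),
                   distance_m = mean(dist$distance_m),
                   mcp95_ha = mean(mcp$area_ha[!mcp$excluded]))),
            class = "foraging_stage")
}
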