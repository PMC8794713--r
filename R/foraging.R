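# Foraging parameters: per-session feeding frequencies, per-point flight
# distances, per-nest MCP95 areas, and their seasonal trend models.

#' Per-session feeding frequencies
#'
#' Visits per hour = landing points of the session / observation minutes x
#' 60; per hour and chick divides by the session's brood size.  All
#' recorded landing points count as visits (an ambiguous landing spot is
#' still a feeding visit).  Sessions that did not end before sunset are
#' excluded, and nests with unclear brood size are excluded entirely.
#'
#' @param sessions Session table.
#' @param landing_points Landing-point table (safe and ambiguous).
#' @param nests Nest table (brood_unclear flag, optional).
#' @return List with \code{records} (per included session) and
#'   \code{exclusions}.
#' @export
feeding_frequencies <- function(sessions, landing_points, nests = NULL) {
  if (any(sessions$duration_min <= 0)) stop("non-positive session duration")
  excl_sunset <- sessions$session_id[!sessions$ended_before_sunset]
  bad_nests <- character(0)
  if (!is.null(nests) && "brood_unclear" %in% names(nests))
    bad_nests <- nests$nest_id[nests$brood_unclear]
  keep <- sessions$ended_before_sunset & !(sessions$nest_id %in% bad_nests) &
    !is.na(sessions$brood_size) & sessions$brood_size >= 1
  ss <- sessions[keep, , drop = FALSE]
  n_land <- table(landing_points$session_id)
  n <- as.integer(n_land[ss$session_id])
  n[is.na(n)] <- 0L
  per_h <- n / ss$duration_min * 60
  rec <- data.frame(session_id = ss$session_id, nest_id = ss$nest_id,
                    date = ss$date, n_visits = n,
                    duration_min = ss$duration_min,
                    brood_size = ss$brood_size,
                    per_h = per_h, per_h_chick = per_h / ss$brood_size,
                    stringsAsFactors = FALSE)
  list(records = rec,
       exclusions = list(sessions_after_sunset = length(excl_sunset),
                         nests_brood_unclear = unique(bad_nests)))
}

#' Flight distances from nests to safe landing points
#'
#' Euclidean distances, no home-range truncation.
#'
#' @param nests Nest table.
#' @param landing_points Landing-point table; only safe points are used.
#' @return data.frame (point_id, session_id, nest_id, distance_m).
#' @export
flight_distances <- function(nests, landing_points) {
  pts <- landing_points[landing_points$safe, , drop = FALSE]
  data.frame(point_id = pts$point_id, session_id = pts$session_id,
             nest_id = pts$nest_id,
             distance_m = point_nest_distances(nests, pts),
             stringsAsFactors = FALSE)
}

#' 95% minimum convex polygon area of a point set
#'
#' Retains the points whose distance to the arithmetic centroid does not
#' exceed the \code{fraction} percentile of those distances (smallest
#' order statistic reaching the fraction, the same convention as the
#' home-range radius), then takes the convex hull.  Nests with fewer than
#' \code{min_points} points are excluded.
#'
#' @param xy Two-column coordinate matrix of one nest's landing points.
#' @param fraction Fraction of points to retain (0.95 for MCP95).
#' @param min_points Minimum number of points.
#' @return List with \code{area_ha} (or NA), \code{excluded},
#'   \code{reason}, \code{n_points}, \code{n_retained}.
#' @export
mcp95 <- function(xy, fraction = 0.95, min_points = 20L) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < min_points)
    return(list(area_ha = NA_real_, excluded = TRUE,
                reason = "insufficient_points", n_points = n,
                n_retained = 0L))
  ctr <- colMeans(xy)
  d <- sqrt((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2)
  ds <- sort(d)
  cutoff <- ds[which(seq_len(n) / n >= fraction - 1e-12)[1]]
  keep <- d <= cutoff + 1e-9
  list(area_ha = convex_hull_area(xy[keep, , drop = FALSE]) / 1e4,
       excluded = FALSE, reason = NA_character_, n_points = n,
       n_retained = sum(keep))
}

#' MCP95 table for all nests
#'
#' @param nests Nest table.
#' @param landing_points Landing-point table (safe points used).
#' @param config A [study_config()] (fraction, minimum points).
#' @return data.frame per nest with area_ha and exclusion status.
#' @export
mcp95_by_nest <- function(nests, landing_points, config = study_config()) {
  pts <- landing_points[landing_points$safe, , drop = FALSE]
  out <- lapply(split(pts, pts$nest_id), function(p)
    mcp95(cbind(p$x, p$y), config$mcp_fraction, config$mcp_min_points))
  data.frame(nest_id = names(out),
             n_points = vapply(out, function(m) m$n_points, 0L),
             area_ha = vapply(out, function(m) m$area_ha, 0),
             excluded = vapply(out, function(m) m$excluded, TRUE),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Session-level covariates shared by the trend models.
session_covariates <- function(sessions, nests, config) {
  data.frame(session_id = sessions$session_id,
             nest_id = sessions$nest_id,
             day = day_of_season(sessions$date, config),
             chick_age = sessions$chick_age_days,
             daytime_min = sessions$start_time_min,
             temperature = sessions$temperature_C,
             wind = sessions$wind_kmh,
             radio = nests$radio_tagged[match(sessions$nest_id,
                                              nests$nest_id)],
             year = nests$year[match(sessions$nest_id, nests$nest_id)],
             stringsAsFactors = FALSE)
}

lmm_coef_table <- function(fit) {
  cf <- stats::coef(summary(fit))
  data.frame(term = rownames(cf), estimate = cf[, "Estimate"],
             se = cf[, "Std. Error"],
             df = if ("df" %in% colnames(cf)) cf[, "df"] else NA_real_,
             t = cf[, "t value"],
             p_value = if ("Pr(>|t|)" %in% colnames(cf)) cf[, "Pr(>|t|)"]
                       else NA_real_,
             row.names = NULL, stringsAsFactors = FALSE)
}

resid_diagnostics <- function(fit) {
  r <- stats::residuals(fit)
  list(resid_quartiles = stats::quantile(r, c(.25, .5, .75)),
       resid_vs_fitted_cor = stats::cor(stats::fitted(fit), r),
       shapiro_p = if (length(r) >= 3 && length(r) <= 5000)
         stats::shapiro.test(r)$p.value else NA_real_)
}

#' Seasonal trend models of the foraging parameters
#'
#' Three linear mixed models (feeding frequency per hour, per hour and
#' chick, flight distance) with fixed effects day of season, chick age,
#' daytime, temperature, wind, radio-tagging and year, a nest random
#' intercept and equal nest weighting (observation weights 1/n per nest);
#' and one linear model for MCP95 area with day of hatching, % of
#' observations before noon, mean temperature, mean wind, radio-tagging
#' and year.  Single-year designs drop the year indicator; rank-deficient
#' designs are an error naming the aliased columns.
#'
#' @param freq Records from [feeding_frequencies()].
#' @param dist Records from [flight_distances()].
#' @param mcp Table from [mcp95_by_nest()].
#' @param sessions,nests Source tables.
#' @param config A [study_config()].
#' @return List of class \code{foraging_trends} with per-model coefficient
#'   tables, sample sizes and residual diagnostics.
#' @export
fit_trend_models <- function(freq, dist, mcp, sessions, nests,
                             config = study_config()) {
  sc <- session_covariates(sessions, nests, config)
  year_term <- function(df) if (length(unique(df$year)) > 1L) "+ year_f" else ""
  fit_lmm <- function(df, response) {
    df$year_f <- factor(df$year)
    df$w <- 1 / as.numeric(table(df$nest_id)[df$nest_id])
    fml <- stats::as.formula(paste(
      response, "~ day + chick_age + daytime_min + temperature + wind",
      "+ radio", year_term(df), "+ (1 | nest_id)"))
    X <- stats::model.matrix(stats::as.formula(paste(
      "~ day + chick_age + daytime_min + temperature + wind + radio",
      year_term(df))), df)
    if (qr(X)$rank < ncol(X))
      stop("rank-deficient design; aliased columns: ",
           paste(colnames(X)[-seq_len(qr(X)$rank)], collapse = ", "))
    fit <- lmerTest::lmer(fml, data = df, weights = df$w, REML = TRUE)
    list(model = fit, coefficients = lmm_coef_table(fit),
         n = nrow(df), n_nests = length(unique(df$nest_id)),
         diagnostics = resid_diagnostics(fit))
  }
  f <- merge(freq$records, sc, by = c("session_id", "nest_id"))
  m_per_h <- fit_lmm(f, "per_h")
  m_per_hc <- fit_lmm(f, "per_h_chick")
  dd <- merge(dist, sc, by = c("session_id", "nest_id"))
  m_dist <- fit_lmm(dd, "distance_m")
  # nest-level MCP design
  mm <- mcp[!mcp$excluded, , drop = FALSE]
  agg <- do.call(rbind, lapply(split(sc, sc$nest_id), function(s)
    data.frame(nest_id = s$nest_id[1],
               pct_before_noon = 100 * mean(s$daytime_min < 720),
               mean_temperature = mean(s$temperature),
               mean_wind = mean(s$wind), stringsAsFactors = FALSE)))
  md <- merge(mm, agg, by = "nest_id")
  md$hatch_day <- day_of_season(
    nests$hatch_date[match(md$nest_id, nests$nest_id)], config)
  md$radio <- nests$radio_tagged[match(md$nest_id, nests$nest_id)]
  md$year <- nests$year[match(md$nest_id, nests$nest_id)]
  md$year_f <- factor(md$year)
  fml <- stats::as.formula(paste(
    "area_ha ~ hatch_day + pct_before_noon + mean_temperature + mean_wind",
    "+ radio", year_term(md)))
  lm_fit <- stats::lm(fml, data = md)
  cf <- stats::coef(summary(lm_fit))
  m_mcp <- list(model = lm_fit,
                coefficients = data.frame(term = rownames(cf),
                                          estimate = cf[, 1], se = cf[, 2],
                                          t = cf[, 3], p_value = cf[, 4],
                                          row.names = NULL,
                                          stringsAsFactors = FALSE),
                n = nrow(md), diagnostics = resid_diagnostics(lm_fit))
  structure(list(frequency_per_h = m_per_h,
                 frequency_per_h_chick = m_per_hc,
                 distance = m_dist, mcp = m_mcp),
            class = "foraging_trends")
}
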