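# Per-habitat seasonal-use models: binary use of a focal habitat versus
# day of season, adjusted for weighted surface area and year, with a nest
# random intercept; prediction curves classified against the availability
# line.

#' Build the design table for a focal habitat
#'
#' One row per in-range safe landing point of every nest whose home range
#' contains the focal habitat; the response is whether the point's mapped
#' habitat equals the focal habitat.  Nests are equally weighted per day
#' of observation via observation weights 1 / (points of that nest on
#' that day).
#'
#' @param focal_habitat Habitat category in focus.
#' @param use_points Point-level table (nest_id, date, habitat) of
#'   in-range safe landing points with their mapped habitat, e.g. from
#'   [pipeline_home_ranges()].
#' @param availability Long per-nest availability table.
#' @param nests Nest table (year).
#' @param config A [study_config()].
#' @return data.frame with response, day, wsa_pct, year, nest, weight.
#' @export
build_seasonal_design <- function(focal_habitat, use_points, availability,
                                  nests, config = study_config()) {
  av <- availability[availability$habitat == focal_habitat &
                       availability$available_pct > 0, , drop = FALSE]
  if (!nrow(av)) stop("no nest has ", focal_habitat, " in its home range")
  pts <- use_points[use_points$nest_id %in% av$nest_id &
                      !is.na(use_points$habitat), , drop = FALSE]
  if (!nrow(pts)) stop("no landing points for focal habitat ", focal_habitat)
  d <- data.frame(nest_id = pts$nest_id,
                  response = as.integer(pts$habitat == focal_habitat),
                  day = day_of_season(pts$date, config),
                  wsa_pct = av$available_pct[match(pts$nest_id, av$nest_id)],
                  year = nests$year[match(pts$nest_id, nests$nest_id)],
                  stringsAsFactors = FALSE)
  key <- paste(d$nest_id, d$day)
  d$weight <- 1 / as.numeric(table(key)[key])
  d$nest <- factor(d$nest_id)
  attr(d, "focal_habitat") <- focal_habitat
  d
}

#' Fit the seasonal-use mixed logistic model
#'
#' \code{response ~ day + wsa_pct + year + (1 | nest)}, binomial logit,
#' maximum likelihood, with the per-day equalizing observation weights.
#' The year indicator is dropped when the design contains a single year.
#'
#' @param design Table from [build_seasonal_design()].
#' @param weighted Use the observation weights (FALSE = unweighted).
#' @return List of class \code{seasonal_fit} with the glmmTMB model and a
#'   Wald coefficient table (estimate, SE, z, p).
#' @export
fit_seasonal_model <- function(design, weighted = TRUE) {
  if (length(unique(design$nest_id)) < 2L) stop("need >= 2 nests")
  if (length(unique(design$response)) < 2L)
    stop("both response classes required")
  design$year_f <- factor(design$year)
  two_years <- nlevels(design$year_f) > 1L
  fml <- if (two_years) response ~ day + wsa_pct + year_f + (1 | nest)
         else response ~ day + wsa_pct + (1 | nest)
  w <- if (weighted) design$weight else rep(1, nrow(design))
  # rescale so sum(w) == sum(w^2) (Kish effective sample size): keeps the
  # per-day nest equalization while calibrating the weighted binomial
  # likelihood's information
  design$obs_weight <- w * sum(w) / sum(w^2)
  fit <- quiet_binomial(
    glmmTMB::glmmTMB(fml, data = design, family = stats::binomial(),
                     weights = obs_weight))
  if (!is.null(fit$fit$convergence) && fit$fit$convergence != 0)
    stop("seasonal model did not converge: ", fit$fit$message)
  cf <- summary(fit)$coefficients$cond
  coefs <- data.frame(term = rownames(cf), estimate = cf[, "Estimate"],
                      se = cf[, "Std. Error"], z = cf[, "z value"],
                      p_value = cf[, "Pr(>|z|)"], row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(model = fit, coefficients = coefs,
                 focal_habitat = attr(design, "focal_habitat"),
                 n_points = nrow(design),
                 n_nests = length(unique(design$nest_id)),
                 mean_wsa_pct = mean(design$wsa_pct[!duplicated(design$nest_id)]),
                 two_years = two_years),
            class = "seasonal_fit")
}

#' Classify predicted use against the availability line
#'
#' Population-level predicted use probability with pointwise 95% CI over
#' season days, at the mean weighted surface area of the included nests
#' and the reference year; a day is \code{preferred} when the lower CI
#' bound exceeds availability (mean_wsa/100, the dashed line),
#' \code{avoided} when the upper bound is below it, else
#' \code{proportional}.
#'
#' @param fit A \code{seasonal_fit}.
#' @param mean_wsa_pct Availability level (default: mean over included
#'   nests).
#' @param days Prediction grid (day of season).
#' @return data.frame with day, fit, lower, upper, classification.
#' @export
classify_against_availability <- function(fit, mean_wsa_pct = NULL,
                                          days = 1:100) {
  if (is.null(mean_wsa_pct)) mean_wsa_pct <- fit$mean_wsa_pct
  if (!is.finite(mean_wsa_pct) || mean_wsa_pct <= 0)
    stop("availability level must be > 0")
  nd <- data.frame(day = days, wsa_pct = mean_wsa_pct,
                   nest = NA_character_, obs_weight = 1)
  if (fit$two_years)
    nd$year_f <- factor(levels(fit$model$frame$year_f)[1],
                        levels = levels(fit$model$frame$year_f))
  pr <- stats::predict(fit$model, newdata = nd, re.form = NA,
                       se.fit = TRUE, type = "link",
                       allow.new.levels = TRUE)
  lo <- stats::plogis(pr$fit - 1.96 * pr$se.fit)
  hi <- stats::plogis(pr$fit + 1.96 * pr$se.fit)
  ref <- mean_wsa_pct / 100
  data.frame(day = days, fit = stats::plogis(pr$fit), lower = lo,
             upper = hi,
             classification = ifelse(lo > ref, "preferred",
                                     ifelse(hi < ref, "avoided",
                                            "proportional")),
             stringsAsFactors = FALSE)
}
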