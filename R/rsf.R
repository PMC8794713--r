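# Resource-selection analysis with pseudo-absences: point generation, the
# nest-equalizing weighting scheme, a binomial additive model with
# penalized splines and a nest random intercept, CI-based
# preference/avoidance classification, and permutation variable
# importance.

#' Draw uniform pseudo-absence points inside a home range
#'
#' Rejection sampling from the bounding square; points falling in coverage
#' gaps or in patches without complete covariates are redrawn until
#' \code{n_points} valid points exist (at most 100x oversampling, then an
#' error naming the nest).
#'
#' @param home_range A \code{home_range}.
#' @param n_points Number of points to draw.
#' @param seed Integer seed.
#' @param valid_patch_ids Optional patch ids with complete covariates;
#'   NULL accepts any mapped patch.
#' @return data.frame with point_id, nest_id, x, y, distance_m, patch_id,
#'   habitat_type.
#' @export
generate_pseudo_absences <- function(home_range, n_points, seed,
                                     valid_patch_ids = NULL) {
  stopifnot(n_points >= 1)
  set.seed(as.integer(seed))
  r <- home_range$radius_m
  cx <- home_range$center[1]; cy <- home_range$center[2]
  got <- data.frame()
  drawn <- 0L
  hr_land <- structure(list(year = NA_integer_, patches = home_range$patches),
                       class = "landscape")
  while (nrow(got) < n_points) {
    if (drawn > 100L * n_points)
      stop("nest ", home_range$nest_id,
           ": cannot place ", n_points, " valid pseudo-absence points")
    m <- max(2L * n_points, 64L)
    x <- stats::runif(m, cx - r, cx + r)
    y <- stats::runif(m, cy - r, cy + r)
    drawn <- drawn + m
    d <- sqrt((x - cx)^2 + (y - cy)^2)
    keep <- d <= r
    loc <- locate_points(hr_land, x[keep], y[keep])
    ok <- !is.na(loc$patch_id)
    if (!is.null(valid_patch_ids)) ok <- ok & loc$patch_id %in% valid_patch_ids
    if (any(ok))
      got <- rbind(got, data.frame(nest_id = home_range$nest_id,
                                   x = x[keep][ok], y = y[keep][ok],
                                   distance_m = d[keep][ok],
                                   patch_id = loc$patch_id[ok],
                                   habitat_type = loc$habitat_type[ok],
                                   stringsAsFactors = FALSE))
  }
  got <- got[seq_len(n_points), , drop = FALSE]
  got$point_id <- sprintf("%s_pa%04d", home_range$nest_id, seq_len(n_points))
  got[, c("point_id", "nest_id", "x", "y", "distance_m", "patch_id",
          "habitat_type")]
}

#' Equalize observation weights per nest
#'
#' Presences of a nest share total weight 1 (1/n_i each) and so do its
#' pseudo-absences (1/m_i each); hence nests are weighted equally and the
#' pseudo-absences carry the same total weight as the documented landing
#' points, per nest and globally.  Nests lacking either kind are dropped
#' with a warning.
#'
#' @param points data.frame with nest_id and kind
#'   ("presence"/"pseudo_absence").
#' @return The table with a \code{weight} column.
#' @export
assign_weights <- function(points) {
  n_pres <- table(points$nest_id[points$kind == "presence"])
  n_abs <- table(points$nest_id[points$kind == "pseudo_absence"])
  good <- intersect(names(n_pres)[n_pres > 0], names(n_abs)[n_abs > 0])
  bad <- setdiff(unique(points$nest_id), good)
  if (length(bad)) {
    warning("nests without presences or absences excluded: ",
            paste(bad, collapse = ", "))
    points <- points[points$nest_id %in% good, , drop = FALSE]
  }
  points$weight <- ifelse(points$kind == "presence",
                          1 / as.numeric(n_pres[points$nest_id]),
                          1 / as.numeric(n_abs[points$nest_id]))
  points
}

# Muffle the expected non-integer binomial-weight chatter from glm/gam.
quiet_binomial <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("non-integer", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

#' Fit the binomial additive resource-selection model
#'
#' \code{kind ~ s(fvc) + s(biomass) + s(shannon) + s(distance) +
#' s(nest, bs = "re")}, binomial with logit link, penalized regression
#' splines with ML smoothness selection, and the per-nest equalizing
#' observation weights.  Records with a missing covariate are dropped and
#' counted before fitting.
#'
#' @param points Weighted point table from [assign_weights()] with
#'   covariate columns fvc_pct, biomass_gm2, shannon_H, distance_m.
#' @param k Basis dimension per smooth (edf values depend on it).
#' @param predictors Covariates to smooth over (default all four).
#' @return List of class \code{rsf_fit}: the mgcv model, per-term summary
#'   (edf, Ref.df, statistic, p), deviance explained, counts.
#' @export
fit_rsf <- function(points, k = 10,
                    predictors = c("fvc_pct", "biomass_gm2", "shannon_H",
                                   "distance_m")) {
  complete <- stats::complete.cases(points[, predictors, drop = FALSE])
  n_dropped <- sum(!complete)
  pts <- points[complete, , drop = FALSE]
  if (length(unique(pts$nest_id)) < 2L) stop("need >= 2 nests")
  if (nrow(pts) < 100L) stop("need >= 100 complete points")
  pts$pres <- as.integer(pts$kind == "presence")
  pts$nest <- factor(pts$nest_id)
  fml <- stats::as.formula(paste(
    "pres ~",
    paste(sprintf("s(%s, k = %d)", predictors, k), collapse = " + "),
    "+ s(nest, bs = 're')"))
  # rescale the weights so that sum(w) == sum(w^2) (Kish effective sample
  # size): the relative weighting (nests equal, absences = presences) is
  # untouched, while Wald/score inference from the weighted likelihood is
  # approximately calibrated -- unscaled per-nest weights sum to ~2 x
  # n_nests and leave the tests powerless, and scaling to n overstates
  # the information in unequal weights
  pts$fit_weight <- pts$weight * sum(pts$weight) / sum(pts$weight^2)
  fit <- quiet_binomial(
    mgcv::gam(fml, family = stats::binomial(), data = pts,
              weights = pts$fit_weight, method = "ML"))
  if (!fit$converged) stop("RSF model did not converge")
  s <- mgcv::summary.gam(fit)
  terms <- data.frame(term = rownames(s$s.table),
                      edf = s$s.table[, "edf"],
                      ref_df = s$s.table[, "Ref.df"],
                      chi_sq = s$s.table[, "Chi.sq"],
                      p_value = s$s.table[, "p-value"],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(model = fit, data = pts, terms = terms,
                 predictors = predictors,
                 deviance_explained = s$dev.expl,
                 n_presence = sum(pts$pres), n_absence = sum(1 - pts$pres),
                 n_nests = nlevels(pts$nest), n_dropped_missing = n_dropped),
            class = "rsf_fit")
}

#' Selection curve and preference/avoidance classification for one smooth
#'
#' Evaluates the centered smooth with its pointwise 95% CI on a grid over
#' the observed predictor range; a grid value is \code{preferred} when the
#' lower bound exceeds the reference level (0 on the centered link scale,
#' the dashed line), \code{avoided} when the upper bound is below it, else
#' \code{neutral}.
#'
#' @param fit An \code{rsf_fit}.
#' @param predictor One of fvc_pct, biomass_gm2, shannon_H, distance_m.
#' @param reference Reference level on the link scale.
#' @param n_grid Grid resolution.
#' @return data.frame with value, effect, lower, upper, classification.
#' @export
classify_selection <- function(fit, predictor, reference = 0, n_grid = 200L) {
  stopifnot(predictor %in% fit$predictors)
  rng <- range(fit$data[[predictor]])
  grid <- seq(rng[1], rng[2], length.out = n_grid)
  nd <- as.data.frame(lapply(fit$data[fit$predictors], stats::median))
  nd$nest <- factor(levels(fit$data$nest)[1], levels = levels(fit$data$nest))
  nd <- nd[rep(1L, n_grid), , drop = FALSE]
  nd[[predictor]] <- grid
  term <- sprintf("s(%s)", predictor)
  pr <- mgcv::predict.gam(fit$model, newdata = nd, type = "terms",
                          terms = term, se.fit = TRUE)
  eff <- as.numeric(pr$fit[, term])
  se <- as.numeric(pr$se.fit[, term])
  lower <- eff - 1.96 * se
  upper <- eff + 1.96 * se
  cls <- ifelse(lower > reference, "preferred",
                ifelse(upper < reference, "avoided", "neutral"))
  data.frame(predictor = predictor, value = grid, effect = eff,
             lower = lower, upper = upper, classification = cls,
             stringsAsFactors = FALSE)
}

#' Permutation variable importance
#'
#' For each predictor (the four covariates and the nest label): permute
#' that column across all points \code{n_reps} times, predict with the
#' unchanged fitted model, and score 1 - Pearson r between original and
#' permuted predictions on the probability scale (floored at 0).  Relative
#' importance normalizes the mean scores to percentages.
#'
#' @param fit An \code{rsf_fit}.
#' @param n_reps Permutation replicates per variable.
#' @param seed Integer seed.
#' @param vars Variables to score (default: the fitted predictors plus the
#'   nest random effect).
#' @return List of class \code{importance_table}: \code{table} with
#'   raw_score and importance_pct per variable, \code{reps} raw scores per
#'   replicate.
#' @export
permutation_importance <- function(fit, n_reps = 100L, seed = 1L,
                                   vars = c(fit$predictors, "nest")) {
  set.seed(as.integer(seed))
  dat <- fit$data
  p0 <- as.numeric(mgcv::predict.gam(fit$model, newdata = dat,
                                     type = "response"))
  if (stats::sd(p0) == 0)
    stop("constant model predictions; permutation importance undefined")
  reps <- matrix(NA_real_, n_reps, length(vars),
                 dimnames = list(NULL, vars))
  for (v in vars) {
    for (i in seq_len(n_reps)) {
      nd <- dat
      nd[[v]] <- nd[[v]][sample.int(nrow(nd))]
      p1 <- as.numeric(mgcv::predict.gam(fit$model, newdata = nd,
                                         type = "response"))
      r <- if (stats::sd(p1) == 0) 1 else stats::cor(p0, p1)
      reps[i, v] <- max(0, 1 - r)
    }
  }
  raw <- colMeans(reps)
  tab <- data.frame(variable = vars, raw_score = as.numeric(raw),
                    importance_pct = 100 * as.numeric(raw) / sum(raw),
                    stringsAsFactors = FALSE)
  structure(list(table = tab[order(-tab$importance_pct), ], reps = reps),
            class = "importance_table")
}
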