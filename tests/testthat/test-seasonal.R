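# Point-level design fixture: in-range use points with known seasonal
# structure in the probability of using the focal habitat.
seasonal_fixture <- function(seed, n_nests = 12L, pts_per_nest = 40L,
                             slope = 0, base_logit = -0.5) {
  set.seed(seed)
  rows <- list(); av <- list()
  for (i in seq_len(n_nests)) {
    nid <- sprintf("n%02d", i)
    day <- sample(5:80, pts_per_nest, replace = TRUE)
    p <- plogis(base_logit + slope * (day - 40) + rnorm(1, 0, 0.3))
    focal <- rbinom(pts_per_nest, 1, p)
    rows[[i]] <- data.frame(
      point_id = sprintf("%s_p%02d", nid, seq_len(pts_per_nest)),
      nest_id = nid,
      date = as.Date("2018-04-24") + day,
      habitat = ifelse(focal == 1, "corn", "winter_wheat"),
      stringsAsFactors = FALSE)
    av[[i]] <- data.frame(nest_id = nid,
                          habitat = c("corn", "winter_wheat"),
                          available_pct = c(30 + runif(1, -10, 10), NA),
                          stringsAsFactors = FALSE)
    av[[i]]$available_pct[2] <- 100 - av[[i]]$available_pct[1]
  }
  nests <- data.frame(nest_id = sprintf("n%02d", seq_len(n_nests)),
                      year = rep(c(2018L, 2019L),
                                 length.out = n_nests),
                      stringsAsFactors = FALSE)
  list(use_points = do.call(rbind, rows), availability = do.call(rbind, av),
       nests = nests)
}

test_that("the seasonal design implements inclusion and per-day weighting", {
  fx <- seasonal_fixture(1L)
  des <- build_seasonal_design("corn", fx$use_points, fx$availability,
                               fx$nests)
  expect_equal(nrow(des), nrow(fx$use_points))
  expect_setequal(unique(des$response), c(0L, 1L))
  # weights: each nest-day carries total weight 1
  key <- paste(des$nest_id, des$day)
  expect_true(all(abs(tapply(des$weight, key, sum) - 1) < 1e-12))
  # a nest without the focal habitat is excluded entirely
  av2 <- fx$availability
  av2$available_pct[av2$nest_id == "n01" & av2$habitat == "corn"] <- 0
  des2 <- build_seasonal_design("corn", fx$use_points, av2, fx$nests)
  expect_false("n01" %in% des2$nest_id)
  # a point's response is 1 only in its own habitat's design
  des_w <- build_seasonal_design("winter_wheat", fx$use_points,
                                 fx$availability, fx$nests)
  both <- merge(des[, c("nest_id", "day", "response")],
                des_w[, c("nest_id", "day", "response")],
                by = c("nest_id", "day"))
  expect_true(all(rowSums(cbind(both$response.x, both$response.y)) <= 2))
  expect_equal(sum(des$response) + sum(des_w$response),
               nrow(fx$use_points))
})

test_that("a seasonally constant habitat yields a null day coefficient", {
  hits <- vapply(1:8, function(s) {
    fx <- seasonal_fixture(s, slope = 0)
    des <- build_seasonal_design("corn", fx$use_points, fx$availability,
                                 fx$nests)
    fit <- fit_seasonal_model(des)
    fit$coefficients$p_value[fit$coefficients$term == "day"] < 0.05
  }, TRUE)
  expect_lte(sum(hits), 2L)
})

test_that("a seasonally declining habitat yields a negative day coefficient", {
  fx <- seasonal_fixture(3L, slope = -0.04)
  des <- build_seasonal_design("corn", fx$use_points, fx$availability,
                               fx$nests)
  fit <- fit_seasonal_model(des)
  day <- fit$coefficients[fit$coefficients$term == "day", ]
  expect_lt(day$estimate, 0)
  expect_lt(day$p_value, 0.01)
})

test_that("prediction curves classify against the availability line", {
  fx <- seasonal_fixture(5L, slope = -0.06)
  des <- build_seasonal_design("corn", fx$use_points, fx$availability,
                               fx$nests)
  fit <- fit_seasonal_model(des)
  cl <- classify_against_availability(fit)
  expect_equal(nrow(cl), 100L)
  expect_true(all(cl$lower <= cl$fit & cl$fit <= cl$upper))
  expect_true(all(cl$classification %in%
                    c("preferred", "proportional", "avoided")))
  # declining use: preference (if any) must come before avoidance
  if (any(cl$classification == "preferred") &&
      any(cl$classification == "avoided"))
    expect_lt(max(cl$day[cl$classification == "preferred"]),
              min(cl$day[cl$classification == "avoided"]))
  # degenerate availability level is a guarded error
  expect_error(classify_against_availability(fit, mean_wsa_pct = 0),
               "> 0")
})
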