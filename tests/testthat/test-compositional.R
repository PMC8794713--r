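# Long-format availability/use tables for a hand-built study.
avail_use_fixture <- function(avail_mat, use_mat, cats) {
  long <- function(m, col) do.call(rbind, lapply(seq_len(nrow(m)),
    function(i) {
      d <- data.frame(nest_id = sprintf("n%02d", i), habitat = cats,
                      v = m[i, ] * 100, stringsAsFactors = FALSE)
      names(d)[3] <- col
      d
    }))
  list(avail = long(avail_mat, "available_pct"),
       use = long(use_mat, "used_pct"))
}

test_that("category selection applies the presence-fraction threshold", {
  av <- data.frame(
    nest_id = rep(sprintf("n%02d", 1:9), each = 3),
    habitat = rep(c("winter_wheat", "sugar_beet", "other:rape"), 9),
    available_pct = c(rep(c(60, 40, 0), 6), rep(c(50, 0, 50), 3)))
  # wheat in 9/9, beet in 6/9, rape in 3/9 home ranges
  expect_equal(select_categories(av, 1 / 3),
               c("winter_wheat", "sugar_beet", "other:rape", "other"))
  expect_equal(select_categories(av, 0.5),
               c("winter_wheat", "sugar_beet", "other"))
  expect_equal(select_categories(av, 1), c("winter_wheat", "other"))
})

test_that("log-ratio differences match hand computation", {
  cats <- c("a", "b")
  fx <- avail_use_fixture(matrix(c(0.25, 0.75), 1), matrix(c(0.5, 0.5), 1),
                          cats)
  cm <- composition_matrix(fx$avail, fx$use, cats)
  d <- logratio_differences(cm, reference = "b")
  # ln(0.5/0.5) - ln(0.25/0.75) = ln 3 = 1.0986
  expect_equal(as.numeric(d), log(3), tolerance = 1e-12)
  # use identical to availability -> all-zero matrix
  m <- matrix(c(0.3, 0.7, 0.6, 0.4), 2, byrow = TRUE)
  fx2 <- avail_use_fixture(m, m, cats)
  d2 <- logratio_differences(composition_matrix(fx2$avail, fx2$use, cats))
  expect_true(all(abs(d2) < 1e-12))
  # zero use is replaced by 1e-4, keeping the output finite
  fx3 <- avail_use_fixture(matrix(c(0.5, 0.5), 1), matrix(c(0, 1), 1), cats)
  d3 <- logratio_differences(composition_matrix(fx3$avail, fx3$use, cats),
                             reference = "b")
  expect_true(is.finite(d3))
  expect_equal(as.numeric(d3), log(1e-4 / 1) - log(1), tolerance = 1e-9)
})

test_that("Wilk's lambda matches the independent MANOVA oracle", {
  set.seed(8)
  for (i in 1:5) {
    d <- matrix(rnorm(7 * 3, mean = 0.3), 7, 3)
    expect_equal(wilks_lambda(d), wilks_oracle(d), tolerance = 1e-10)
  }
  # 1-D closed form: lambda = 1 - n dbar^2 / sum d^2
  d1 <- matrix(c(0.2, 0.5, -0.1, 0.4, 0.3), 5, 1)
  expect_equal(wilks_lambda(d1),
               1 - 5 * mean(d1)^2 / sum(d1^2), tolerance = 1e-12)
  # no departure and sign-symmetric data give lambda = 1
  expect_equal(wilks_lambda(matrix(0, 5, 2)), 1)
  sym <- rbind(matrix(rnorm(6), 3, 2), -matrix(rnorm(6), 3, 2))
  sym <- rbind(sym, -sym)
  expect_equal(wilks_lambda(sym), 1, tolerance = 1e-12)
  expect_error(wilks_lambda(matrix(rnorm(4), 2, 2)), "rows")
})

test_that("lambda is reference-invariant and shrinks with scaled departures", {
  set.seed(10)
  cats <- c("a", "b", "c", "d")
  av <- matrix(rgamma(6 * 4, 3), 6); av <- av / rowSums(av)
  us <- matrix(rgamma(6 * 4, 3), 6); us <- us / rowSums(us)
  fx <- avail_use_fixture(av, us, cats)
  cm <- composition_matrix(fx$avail, fx$use, cats)
  lams <- vapply(cats, function(ref)
    wilks_lambda(logratio_differences(cm, reference = ref)), 0)
  expect_lt(max(lams) - min(lams), 1e-8)
  # scaling all difference vectors up cannot increase lambda
  d <- logratio_differences(cm)
  expect_lte(wilks_lambda(d * 2), wilks_lambda(d) + 1e-12)
  expect_true(wilks_lambda(d) > 0 && wilks_lambda(d) <= 1)
})

test_that("randomization p-value matches exhaustive sign-flip enumeration", {
  # lambda = 1 can never be beaten: p = 1
  d0 <- matrix(0, 5, 2)
  expect_equal(randomization_test(d0, 99L, seed = 1L)$p_value, 1)
  # n = 8 nests: compare against the exact 2^8 enumeration
  set.seed(20)
  d <- matrix(rnorm(8 * 2, mean = 0.45, sd = 0.8), 8, 2)
  obs <- wilks_lambda(d)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 8)))
  lam_all <- apply(signs, 1, function(s) wilks_lambda(d * s))
  p_exact <- mean(lam_all <= obs + 1e-12)
  p_rand <- randomization_test(d, 10000L, seed = 2L)$p_value
  expect_lt(abs(p_rand - p_exact), 0.02)
})

test_that("the ranking matrix equals a direct pairwise t-test oracle", {
  set.seed(30)
  cats <- c("a", "b", "c")
  av <- matrix(rgamma(4 * 3, 4), 4); av <- av / rowSums(av)
  us <- matrix(rgamma(4 * 3, 4), 4); us <- us / rowSums(us)
  fx <- avail_use_fixture(av, us, cats)
  cm <- composition_matrix(fx$avail, fx$use, cats)
  rk <- ranking_matrix(cm)
  for (j in 1:3) for (k in 1:3) {
    if (j == k) next
    dd <- log(cm$use[, j] / cm$use[, k]) -
      log(cm$avail[, j] / cm$avail[, k])
    tt <- t.test(dd)
    expect_equal(rk$mean_diff[cats[j], cats[k]], mean(dd),
                 tolerance = 1e-10)
    expect_equal(rk$t_stat[cats[j], cats[k]], unname(tt$statistic),
                 tolerance = 1e-10)
  }
  # a category used far above availability against all others everywhere
  # takes the top rank D - 1
  us2 <- cbind(0.9, av[, 2:3] / rowSums(av[, 2:3]) * 0.1)
  fx2 <- avail_use_fixture(av, us2 / rowSums(us2), cats)
  cm2 <- composition_matrix(fx2$avail, fx2$use, cats)
  rk2 <- ranking_matrix(cm2)
  expect_equal(unname(rk2$ranks["a"]), 2L)
  # use == availability: all mean differences 0, ranks tied at 0
  fx3 <- avail_use_fixture(av, av, cats)
  rk3 <- ranking_matrix(composition_matrix(fx3$avail, fx3$use, cats))
  expect_true(all(abs(rk3$mean_diff) < 1e-12, na.rm = TRUE))
  expect_true(all(rk3$ranks == 0))
})

test_that("missing availability cells are mean-substituted, not fatal", {
  cats <- c("a", "b", "c")
  av <- matrix(c(0.5, 0.5, 0.0,
                 0.4, 0.4, 0.2,
                 0.3, 0.3, 0.4,
                 0.2, 0.6, 0.2), 4, byrow = TRUE)
  us <- matrix(c(0.6, 0.4, 0.0,
                 0.3, 0.5, 0.2,
                 0.4, 0.2, 0.4,
                 0.3, 0.5, 0.2), 4, byrow = TRUE)
  fx <- avail_use_fixture(av, us, cats)
  cm <- composition_matrix(fx$avail, fx$use, cats)
  d <- logratio_differences(cm, reference = "a")
  expect_true(all(is.finite(d)))
  # nest 1 has no availability of c; its cell equals the column mean of
  # the defined nests
  d_nomiss <- logratio_differences(cm, reference = "a",
                                   drop_incomplete = TRUE)
  expect_equal(nrow(d_nomiss), 3L)
  expect_equal(d["n01", "c"], mean(d_nomiss[, "c"]), tolerance = 1e-12)
})
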