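# Compositional analysis of habitat use versus availability: category
# selection, log-ratio differences, one-sample Wilk's lambda, a sign-flip
# randomization p-value, and the pairwise ranking matrix.

#' Select compositional habitat categories
#'
#' Habitats present (available_pct > 0) in at least \code{threshold} of all
#' home ranges get their own category; the rest is pooled as "other".
#'
#' @param availability Long table (nest_id, habitat, available_pct).
#' @param threshold Presence fraction required for an own category.
#' @return Character vector of categories ending in "other".
#' @export
select_categories <- function(availability, threshold = 1 / 3) {
  nests <- unique(availability$nest_id)
  present <- availability[availability$available_pct > 0, , drop = FALSE]
  frac <- table(unique(present[, c("nest_id", "habitat")])$habitat) /
    length(nests)
  own <- names(frac)[frac >= threshold - 1e-12]
  own <- own[order(-frac[own])]
  c(own, "other")
}

#' Build the use and availability composition matrices
#'
#' Pools habitats outside \code{categories} into "other" and normalizes
#' each nest's row to proportions.  Nests without any in-range use are
#' dropped (reported via attribute \code{dropped}).
#'
#' @param availability,use Long tables (nest_id, habitat,
#'   available_pct/used_pct).
#' @param categories Category vector from [select_categories()].
#' @return List of class \code{composition_matrix} with \code{use},
#'   \code{avail} (nests x categories matrices) and \code{categories}.
#' @export
composition_matrix <- function(availability, use, categories) {
  pool <- function(tab, col) {
    tab$cat <- ifelse(tab$habitat %in% categories, tab$habitat, "other")
    x <- tapply(tab[[col]], list(tab$nest_id, tab$cat), sum, default = 0)
    m <- matrix(0, nrow(x), length(categories),
                dimnames = list(rownames(x), categories))
    m[, intersect(colnames(x), categories)] <-
      x[, intersect(colnames(x), categories)]
    m
  }
  av <- pool(availability, "available_pct")
  us <- pool(use, "used_pct")
  # a category with no availability and no use anywhere (e.g. an empty
  # "other" pool when every habitat got its own category) carries no
  # information and would leave log-ratios undefined
  empty <- colSums(av) == 0 & colSums(us) == 0
  if (any(empty)) {
    av <- av[, !empty, drop = FALSE]
    us <- us[, !empty, drop = FALSE]
    categories <- categories[!empty]
  }
  if (length(categories) < 2L) stop("need >= 2 non-empty categories")
  used_nests <- rownames(us)[rowSums(us) > 0]
  common <- intersect(rownames(av), used_nests)
  dropped <- setdiff(rownames(av), common)
  av <- av[common, , drop = FALSE]
  us <- us[common, , drop = FALSE]
  av <- av / rowSums(av)
  us <- us / rowSums(us)
  structure(list(use = us, avail = av, categories = categories),
            class = "composition_matrix", dropped = dropped)
}

#' Log-ratio use-availability differences
#'
#' \eqn{d_{ij} = \ln(u_{ij}/u_{i,ref}) - \ln(a_{ij}/a_{i,ref})}.  Zero used
#' proportions are replaced by \code{zero_replace} (0.01% by convention,
#' no renormalization) before transforming.  A category unavailable to a
#' nest yields a missing cell, filled by the column mean over nests where
#' it is defined (mean substitution); \code{drop_incomplete = TRUE} deletes
#' such nests instead.
#'
#' @param cm A [composition_matrix()].
#' @param reference Reference category; the default picks the category
#'   available to the most nests (lambda is reference-invariant, but a
#'   ubiquitous reference minimizes missing cells).
#' @param zero_replace Replacement for zero used proportions.
#' @param drop_incomplete Drop nests with missing cells instead of mean
#'   substitution.
#' @return Nests x (D-1) matrix of differences.
#' @export
logratio_differences <- function(cm, reference = NULL, zero_replace = 1e-4,
                                 drop_incomplete = FALSE) {
  cats <- cm$categories
  if (is.null(reference))
    reference <- cats[which.max(colSums(cm$avail > 0))]
  stopifnot(reference %in% cats)
  u <- cm$use
  u[u == 0] <- zero_replace
  a <- cm$avail
  a[a == 0] <- NA            # unavailable category -> missing cell
  others <- setdiff(cats, reference)
  d <- log(u[, others, drop = FALSE] / u[, reference]) -
    log(a[, others, drop = FALSE] / a[, reference])
  if (drop_incomplete) {
    d <- d[stats::complete.cases(d), , drop = FALSE]
  } else {
    for (j in seq_len(ncol(d))) {
      miss <- is.na(d[, j])
      if (all(miss)) stop("category ", others[j],
                          " undefined for every nest; pool categories")
      d[miss, j] <- mean(d[!miss, j])
    }
  }
  d
}

#' One-sample Wilk's lambda of a difference matrix
#'
#' \eqn{\Lambda = \det(R_1)/\det(R_0)} with \eqn{R_1} the SSCP about the
#' mean and \eqn{R_0} the SSCP about zero; 1 means no departure from
#' use = availability, smaller values stronger selection.  The all-zero
#' matrix returns 1 by convention.
#'
#' @param d Nests x (D-1) difference matrix.
#' @return Lambda in (0, 1].
#' @export
wilks_lambda <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < ncol(d) + 1L)
    stop("need at least D nests (rows >= columns + 1)")
  if (all(d == 0)) return(1)
  r0 <- crossprod(d)
  r1 <- crossprod(sweep(d, 2, colMeans(d)))
  det0 <- det(r0)
  if (!is.finite(det0) || det0 <= 1e-300)
    stop("singular SSCP matrix; consider pooling categories")
  max(0, min(1, det(r1) / det0))
}

#' Randomization p-value for Wilk's lambda
#'
#' The null flips the sign of each nest's difference vector independently
#' with probability 1/2 (exchangeability of the use and availability
#' labels within a nest); p = (1 + #\{lambda_rand <= lambda_obs\}) /
#' (1 + n_iter), one-sided in lambda.
#'
#' @param d Difference matrix.
#' @param n_iter Randomization iterations.
#' @param seed Integer seed.
#' @return List with lambda, p_value, n_iter.
#' @export
randomization_test <- function(d, n_iter = 1000L, seed = 1L) {
  stopifnot(n_iter >= 1)
  set.seed(as.integer(seed))
  d <- as.matrix(d)
  obs <- wilks_lambda(d)
  n <- nrow(d)
  count <- 0L
  for (i in seq_len(n_iter)) {
    s <- sample(c(-1, 1), n, replace = TRUE)
    if (wilks_lambda(d * s) <= obs + 1e-12) count <- count + 1L
  }
  list(lambda = obs, p_value = (1 + count) / (1 + n_iter), n_iter = n_iter)
}

#' Pairwise ranking matrix of habitat categories
#'
#' For each ordered category pair (j, k): the mean over nests of
#' \eqn{\ln(u_j/u_k) - \ln(a_j/a_k)} and its one-sample t statistic
#' (computed over nests where both categories are available; zero use
#' replaced as in [logratio_differences()]).  A category's rank is the
#' number of categories it beats (positive mean difference); significance
#' is marked at |t| > t(0.975, n-1).
#'
#' @param cm A [composition_matrix()].
#' @param zero_replace Replacement for zero used proportions.
#' @return List of class \code{ranking_matrix} with \code{mean_diff},
#'   \code{t_stat}, \code{signif} matrices and \code{ranks}.
#' @export
ranking_matrix <- function(cm, zero_replace = 1e-4) {
  cats <- cm$categories
  D <- length(cats)
  u <- cm$use
  u[u == 0] <- zero_replace
  a <- cm$avail
  md <- tmat <- sig <- matrix(NA_real_, D, D, dimnames = list(cats, cats))
  for (j in seq_len(D)) for (k in seq_len(D)) {
    if (j == k) next
    ok <- cm$avail[, j] > 0 & cm$avail[, k] > 0
    if (sum(ok) < 3L) next
    dd <- log(u[ok, j] / u[ok, k]) - log(a[ok, j] / a[ok, k])
    md[j, k] <- mean(dd)
    se <- stats::sd(dd) / sqrt(length(dd))
    tmat[j, k] <- if (se > 0) mean(dd) / se else 0
    sig[j, k] <- as.numeric(abs(tmat[j, k]) >
                              stats::qt(0.975, length(dd) - 1L))
  }
  ranks <- apply(md, 1, function(r) sum(r > 0, na.rm = TRUE))
  structure(list(mean_diff = md, t_stat = tmat, signif = sig,
                 ranks = sort(ranks, decreasing = TRUE)),
            class = "ranking_matrix")
}

#' Full compositional analysis
#'
#' Category selection, composition matrices, log-ratio differences,
#' Wilk's lambda with its randomization p-value, and the ranking matrix.
#'
#' @param availability,use Long per-nest tables.
#' @param config A [study_config()] (threshold, iterations, seed).
#' @param drop_incomplete Passed to [logratio_differences()].
#' @return List of class \code{compositional_result}.
#' @export
compositional_analysis <- function(availability, use,
                                   config = study_config(),
                                   drop_incomplete = FALSE) {
  cats <- select_categories(availability, config$frequent_habitat_fraction)
  cm <- composition_matrix(availability, use, cats)
  d <- logratio_differences(cm, drop_incomplete = drop_incomplete)
  rt <- randomization_test(d, config$n_randomizations, config$rng_seed)
  rk <- ranking_matrix(cm)
  structure(list(categories = cm$categories, matrix = cm, differences = d,
                 lambda = rt$lambda, p_value = rt$p_value,
                 n_randomizations = rt$n_iter, ranking = rk),
            class = "compositional_result")
}
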