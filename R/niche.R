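# Bioclimatic niche analysis: standardized PCA of an occurrence table and
# directional niche-region overlap between two labels. The alpha-niche
# region of a label is the central alpha-probability ellipsoid of its
# multivariate normal climate distribution; overlap(A -> B) is the
# probability that a draw from A's distribution falls inside B's region.

occ_matrix <- function(tbl) {
  num <- vapply(tbl, is.numeric, TRUE)
  as.matrix(tbl[, num, drop = FALSE])
}

#' PCA of an occurrence table with percent variance explained
#'
#' Columns are z-scored (zero mean, unit variance) before the
#' eigendecomposition unless the table is flagged as pre-standardized;
#' constant columns are dropped with a warning. Percent variances sum to 100.
#'
#' @param tbl data frame with a `label` column and numeric variable columns
#'   (e.g. from [simulate_occurrences()] or an occurrence CSV).
#' @param standardized set `TRUE` when the table is already standardized, to
#'   skip the z-scoring.
#' @return list with `percent` (variance explained per component),
#'   `loadings` (variables x components), `scores`, and `dropped` (constant
#'   columns removed).
#' @export
pca_variance <- function(tbl, standardized = FALSE) {
  x <- occ_matrix(tbl)
  if (nrow(x) < 3) stop("need at least 3 records for a PCA")
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped)) {
    warning("dropping constant columns: ", paste(dropped, collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = !standardized)
  pct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  list(percent = pct, loadings = pc$rotation, scores = pc$x,
       dropped = dropped)
}

label_stats <- function(tbl, label) {
  x <- occ_matrix(tbl)[tbl$label == label, , drop = FALSE]
  if (nrow(x) < 2) stop("label '", label, "' has fewer than 2 records")
  if (nrow(x) < 20) warning("label '", label, "' has fewer than 20 records")
  mu <- colMeans(x)
  S <- stats::cov(x)
  if (!all(is.finite(S)) || min(eigen(S, symmetric = TRUE,
                                      only.values = TRUE)$values) <= 1e-12)
    stop("singular covariance for label '", label, "'")
  list(x = x, n = nrow(x), mu = mu, S = S)
}

rmvnorm_chol <- function(k, mu, S) {
  d <- length(mu)
  z <- matrix(stats::rnorm(k * d), k, d) %*% chol(S)
  sweep(z, 2, mu, `+`)
}

# one Monte Carlo overlap estimate: P(X in alpha-region of (muB, SB)),
# X ~ N(muA, SA)
mc_overlap <- function(muA, SA, muB, SB, alpha, draws) {
  d <- length(muA)
  x <- rmvnorm_chol(draws, muA, SA)
  md2 <- stats::mahalanobis(x, muB, SB)
  mean(md2 <= stats::qchisq(alpha, df = d))
}

# normal-inverse-Wishart posterior draw under the noninformative prior
# p(mu, Sigma) ~ |Sigma|^-((d+1)/2): Sigma ~ invWishart(n-1, S_c),
# mu | Sigma ~ N(xbar, Sigma/n), with S_c the centered scatter matrix.
niw_draw <- function(st) {
  d <- ncol(st$x)
  Sc <- st$S * (st$n - 1)
  W <- stats::rWishart(1, df = st$n - 1, Sigma = solve(Sc))[, , 1]
  Sigma <- solve(W)
  mu <- drop(rmvnorm_chol(1, st$mu, Sigma / st$n))
  list(mu = mu, S = Sigma)
}

#' Directional niche overlap between two labels
#'
#' The niche region of label B is
#' `{x : (x - mu_B)' Sigma_B^-1 (x - mu_B) <= chisq_d(alpha)}`; the overlap
#' `A -> B` is the probability that a draw from A's distribution lands in
#' B's region, estimated by Monte Carlo. The plug-in estimator uses the
#' sample mean/covariance; the Bayesian estimator (default) draws
#' `posterior_draws` parameter sets per label from a normal-inverse-Wishart
#' posterior with a noninformative prior and reports the posterior mean and
#' central 95% interval. Overlap is directional: both directions are always
#' reported.
#'
#' @param tbl occurrence data frame (`label` column + numeric variables).
#' @param labelA,labelB the two labels.
#' @param alpha niche-region probability mass (default 0.95).
#' @param draws Monte Carlo points (per posterior draw for the Bayesian
#'   estimator).
#' @param estimator `"bayesian"` or `"plugin"`.
#' @param posterior_draws posterior parameter draws per label (Bayesian).
#' @param seed integer RNG seed.
#' @return object of class `niche_overlap`: for each direction the point
#'   estimate (posterior mean when Bayesian) and, when Bayesian, the central
#'   95% interval; plus the settings used.
#' @export
niche_overlap <- function(tbl, labelA = "wild", labelB = "cultivated",
                          alpha = 0.95, draws = 1000,
                          estimator = c("bayesian", "plugin"),
                          posterior_draws = 1000, seed = 1) {
  estimator <- match.arg(estimator)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  set.seed(seed)
  A <- label_stats(tbl, labelA); B <- label_stats(tbl, labelB)
  if (estimator == "plugin") {
    ab <- mc_overlap(A$mu, A$S, B$mu, B$S, alpha, draws)
    ba <- mc_overlap(B$mu, B$S, A$mu, A$S, alpha, draws)
    res <- list(ab = list(mean = ab), ba = list(mean = ba))
  } else {
    samp <- matrix(0, posterior_draws, 2)
    for (i in seq_len(posterior_draws)) {
      pa <- niw_draw(A); pb <- niw_draw(B)
      samp[i, 1] <- mc_overlap(pa$mu, pa$S, pb$mu, pb$S, alpha, draws)
      samp[i, 2] <- mc_overlap(pb$mu, pb$S, pa$mu, pa$S, alpha, draws)
    }
    ci <- apply(samp, 2, stats::quantile, c(0.025, 0.975))
    res <- list(ab = list(mean = mean(samp[, 1]), lower = ci[1, 1],
                          upper = ci[2, 1]),
                ba = list(mean = mean(samp[, 2]), lower = ci[1, 2],
                          upper = ci[2, 2]))
  }
  out <- list(labelA = labelA, labelB = labelB, alpha = alpha,
              estimator = estimator, draws = draws,
              posterior_draws = if (estimator == "bayesian") posterior_draws,
              a_in_b = res$ab, b_in_a = res$ba)
  class(out) <- "niche_overlap"
  out
}

#' @export
print.niche_overlap <- function(x, ...) {
  fmt <- function(r) {
    s <- sprintf("%.3f", r$mean)
    if (!is.null(r$lower))
      s <- sprintf("%s [%.3f, %.3f]", s, r$lower, r$upper)
    s
  }
  cat(sprintf("niche overlap (%s estimator, alpha = %.2f)\n",
              x$estimator, x$alpha))
  cat(sprintf("  P(%s in %s niche region) = %s\n", x$labelA, x$labelB,
              fmt(x$a_in_b)))
  cat(sprintf("  P(%s in %s niche region) = %s\n", x$labelB, x$labelA,
              fmt(x$b_in_a)))
  invisible(x)
}
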