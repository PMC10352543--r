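# Sliding-window age-course differential analysis (SWAN). Generic over
# any feature x sample matrix: percent methylation or, e.g., protein
# abundance.

#' SWAN configuration
#'
#' @param window_width window width in years (default 10).
#' @param step center step in years (default 1).
#' @param q_alpha per-center BH significance level (default 0.05).
#' @param min_per_window minimum subjects per window (default 5).
#' @param covariates optional adjustment columns (off by default; the
#'   two-group comparison is then the plain two-variable linear model,
#'   i.e. a pooled two-sample t-test).
#' @param mode `"adjacent"` (default) compares the younger window
#'   `[c - width, c)` against the older window `[c, c + width)`;
#'   `"outside"` compares subjects inside `[c - width/2, c + width/2]`
#'   against all others (the variant that peaks at the center of a
#'   transient, episode-like change).
#' @return A `swan_config` list.
#' @export
swan_config <- function(window_width = 10, step = 1, q_alpha = 0.05,
                        min_per_window = 5L, covariates = NULL,
                        mode = c("adjacent", "outside")) {
  if (window_width <= 0 || step <= 0)
    stop("window_width and step must be positive", call. = FALSE)
  if (min_per_window < 2L)
    stop("min_per_window must be >= 2", call. = FALSE)
  structure(list(window_width = window_width, step = step,
                 q_alpha = q_alpha, min_per_window = min_per_window,
                 covariates = covariates, mode = match.arg(mode)),
            class = "swan_config")
}

swan_groups <- function(ages, center, config) {
  w <- config$window_width
  if (config$mode == "adjacent") {
    g1 <- ages >= center - w & ages < center        # younger
    g2 <- ages >= center & ages < center + w        # older
  } else {
    g2 <- abs(ages - center) <= w / 2               # inside
    g1 <- !g2                                       # outside
  }
  list(ref = g1, cmp = g2)
}

#' Valid SWAN center ages
#'
#' Integer-spaced centers whose two age windows lie within the
#' observed age range (`c - width >= min(age)` and
#' `c <= max(age) - width`) and each hold at least `min_per_window`
#' subjects; boundary centers whose windows would reach past the data
#' are excluded (they would otherwise report artifactual hits).
#'
#' @param ages subject ages in years.
#' @param config a [swan_config()].
#' @return Increasing numeric vector of center ages; errors if none is
#'   valid.
#' @export
swan_centers <- function(ages, config = swan_config()) {
  if (length(ages) < 2L * config$min_per_window)
    stop("too few subjects for any window", call. = FALSE)
  w <- config$window_width
  lo <- ceiling(min(ages) + w)
  hi <- floor(max(ages) - w)
  if (hi < lo) stop("no valid SWAN centers", call. = FALSE)
  cand <- seq(lo, hi, by = config$step)
  ok <- vapply(cand, function(c) {
    g <- swan_groups(ages, c, config)
    sum(g$ref) >= config$min_per_window &&
      sum(g$cmp) >= config$min_per_window
  }, logical(1L))
  if (!any(ok)) stop("no valid SWAN centers", call. = FALSE)
  cand[ok]
}

#' Per-feature test at one SWAN center
#'
#' Linear model of feature value on intercept + window indicator
#' (plus optional covariates); the two-sided p-value of the indicator
#' coefficient. Without covariates this is algebraically the pooled
#' equal-variance two-sample t-test, computed here in closed form for
#' all features at once.
#'
#' @param feature_matrix features x samples numeric matrix (`NA` =
#'   missing).
#' @param ages subject ages aligned with columns.
#' @param center a center age from [swan_centers()].
#' @param config a [swan_config()].
#' @param samples covariate table (only needed when
#'   `config$covariates` is set).
#' @return Numeric vector of p-values per feature; `NA` where a window
#'   falls below `min_per_window` observed values or the feature has
#'   zero variance in both windows.
#' @export
swan_test <- function(feature_matrix, ages, center,
                      config = swan_config(), samples = NULL) {
  feature_matrix <- as.matrix(feature_matrix)
  g <- swan_groups(ages, center, config)
  if (!is.null(config$covariates))
    return(swan_test_lm(feature_matrix, g, config, samples))
  Y1 <- feature_matrix[, g$ref, drop = FALSE]
  Y2 <- feature_matrix[, g$cmp, drop = FALSE]
  n1 <- rowSums(!is.na(Y1)); n2 <- rowSums(!is.na(Y2))
  m1 <- rowMeans(Y1, na.rm = TRUE); m2 <- rowMeans(Y2, na.rm = TRUE)
  ss1 <- rowSums((Y1 - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((Y2 - m2)^2, na.rm = TRUE)
  df <- n1 + n2 - 2L
  s2 <- (ss1 + ss2) / pmax(df, 1L)
  tstat <- (m2 - m1) / sqrt(s2 * (1 / n1 + 1 / n2))
  p <- 2 * pt(-abs(tstat), df)
  # sd = 0: identical groups carry no evidence (t = 0, p = 1) unless
  # the means differ, in which case separation is perfect
  zero_sd <- !is.na(s2) & s2 == 0
  p[zero_sd & (m2 - m1) != 0] <- 0
  p[zero_sd & (m2 - m1) == 0] <- 1
  p[n1 < config$min_per_window | n2 < config$min_per_window] <- NA_real_
  unname(p)
}

swan_test_lm <- function(Y, g, config, samples) {
  stopifnot_cols(samples, config$covariates, "samples")
  keep <- g$ref | g$cmp
  d <- samples[keep, config$covariates, drop = FALSE]
  d$.win <- as.integer(g$cmp[keep])
  X <- stats::model.matrix(stats::reformulate(c(".win",
                                                config$covariates)), d)
  wcol <- match(".win", colnames(X))
  apply(Y[, keep, drop = FALSE], 1L, function(y) {
    obs <- !is.na(y)
    if (sum(obs & d$.win == 1L) < config$min_per_window ||
        sum(obs & d$.win == 0L) < config$min_per_window)
      return(NA_real_)
    Xo <- X[obs, , drop = FALSE]
    if (qr(Xo)$rank < ncol(Xo)) return(NA_real_)
    fit <- stats::lm.fit(Xo, y[obs])
    df <- sum(obs) - ncol(Xo)
    if (df < 1L) return(NA_real_)
    V <- chol2inv(chol(crossprod(Xo)))
    se <- sqrt(sum(fit$residuals^2) / df * V[wcol, wcol])
    if (se == 0) return(if (fit$coefficients[wcol] == 0) NA_real_ else 0)
    2 * pt(-abs(fit$coefficients[wcol] / se), df)
  })
}

#' Sliding-window profile over all valid centers
#'
#' Runs [swan_test()] at every valid center, applies BH correction
#' across features within each center, counts features with
#' `q < q_alpha`, and collects the union of features significant at
#' any center.
#'
#' @inheritParams swan_test
#' @return A `swan_profile`: list with `profile` (data.frame `center`,
#'   `n_tested`, `n_significant`), `p_values` and `q_values`
#'   (features x centers matrices) and `union_set` (row indices, named
#'   if `feature_matrix` has rownames).
#' @export
swan_profile <- function(feature_matrix, ages, config = swan_config(),
                         samples = NULL) {
  feature_matrix <- as.matrix(feature_matrix)
  centers <- swan_centers(ages, config)
  P <- vapply(centers, function(c)
    swan_test(feature_matrix, ages, c, config, samples),
    numeric(nrow(feature_matrix)))
  P <- matrix(P, nrow = nrow(feature_matrix),
              dimnames = list(rownames(feature_matrix), centers))
  Q <- apply(P, 2L, bh_adjust)
  Q <- matrix(Q, nrow = nrow(P), dimnames = dimnames(P))
  sig <- !is.na(Q) & Q < config$q_alpha
  union_idx <- which(rowSums(sig) > 0)
  structure(list(
    profile = data.frame(center = centers,
                         n_tested = colSums(!is.na(P)),
                         n_significant = colSums(sig)),
    p_values = P, q_values = Q,
    union_set = if (!is.null(rownames(P))) rownames(P)[union_idx]
                else union_idx,
    config = config), class = "swan_profile")
}

#' @export
print.swan_profile <- function(x, ...) {
  pr <- x$profile
  cat(sprintf("SWAN profile: %d centers (ages %g-%g), %d features\n",
              nrow(pr), min(pr$center), max(pr$center),
              nrow(x$p_values)))
  peak <- pr$center[which.max(pr$n_significant)]
  cat(sprintf(
    "  peak: %d significant features (q < %g) at center age %g\n",
    max(pr$n_significant), x$config$q_alpha, peak))
  cat(sprintf("  union of significant features: %d\n",
              length(x$union_set)))
  invisible(x)
}

#' Plot the number of significant features per center age
#' @param x a `swan_profile`.
#' @param ... passed to `plot()`.
#' @return `x`, invisibly.
#' @method plot swan_profile
#' @export
plot.swan_profile <- function(x, ...) {
  pr <- x$profile
  plot(pr$center, pr$n_significant, type = "b", pch = 16,
       xlab = "center age (years)",
       ylab = sprintf("features with q < %g", x$config$q_alpha), ...)
  invisible(x)
}
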