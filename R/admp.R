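# Per-CpG linear regression of percent methylation on age (aDMPs).

#' Benjamini-Hochberg adjustment
#'
#' Thin validating wrapper around `stats::p.adjust(method = "BH")`;
#' `NA` p-values are passed through untouched and do not count toward
#' the number of tests.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  q <- p
  ok <- !is.na(p)
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}

#' Per-CpG age regression (aDMP calling)
#'
#' For each locus, ordinary least squares of percent methylation on
#' age plus covariates (categoricals expanded to indicators). Missing
#' entries (loci with zero coverage in a sample) are dropped listwise
#' per locus. The age coefficient is reported in percentage points per
#' year with its standard error and a two-sided t-test on
#' `n_used - k - 1` degrees of freedom (`k` = number of model terms).
#' A locus is called age-associated when `p_value < alpha` (the
#' package also reports BH q-values for FDR-based selection).
#'
#' An optional random-intercept mode (`random = "batch"` etc., fitted
#' with lmerTest when installed) is provided for designs with repeated
#' structure; with one observation per subject no random effect is
#' identifiable and plain OLS is the default.
#'
#' @param pct loci x samples matrix of percent methylation (see
#'   [percent_methylation()]); `NA` marks missing.
#' @param samples per-subject covariate table; must contain `age` and
#'   every requested covariate; rows must match `ncol(pct)` in order.
#' @param covariates character vector of adjustment columns (default
#'   `c("sex", "race", "bmi")`; use `character()` for age only).
#' @param alpha significance level on the per-CpG p-value
#'   (default 0.05).
#' @param loci optional data.frame (`chrom`, `pos`) to carry locus
#'   coordinates into the result.
#' @param random optional grouping column for a random intercept.
#' @return An `admp_fit` data.frame with columns `beta_age`, `se`,
#'   `t_value`, `p_value`, `q_value`, `n_used`, `flag` (`"ok"`,
#'   `"zero_variance"`, `"collinear"`, `"insufficient_data"`) and
#'   `significant`; flagged loci carry `NA` statistics and are excluded
#'   from the BH adjustment.
#' @export
fit_admp <- function(pct, samples, covariates = c("sex", "race", "bmi"),
                     alpha = 0.05, loci = NULL, random = NULL) {
  pct <- as.matrix(pct)
  if (ncol(pct) != nrow(samples))
    stop("ncol(pct) must equal nrow(samples)", call. = FALSE)
  stopifnot_cols(samples, c("age", covariates), "samples")
  if (!is.null(random))
    return(fit_admp_mixed(pct, samples, covariates, alpha, loci, random))
  form <- stats::reformulate(c("age", covariates))
  X <- stats::model.matrix(form, data = samples)
  p_terms <- ncol(X)
  n <- nrow(X)
  J <- nrow(pct)
  beta <- se <- tval <- pval <- rep(NA_real_, J)
  n_used <- integer(J)
  flag <- rep("ok", J)

  qr_global <- qr(X)
  global_ok <- qr_global$rank == p_terms
  age_col <- match("age", colnames(X))

  n_obs <- rowSums(!is.na(pct))
  row_var <- apply(pct, 1L, function(y) stats::var(y[!is.na(y)]))
  zero_var <- !is.na(row_var) & row_var == 0
  too_few <- n_obs < p_terms + 1L
  complete <- n_obs == n & !zero_var & !too_few

  if (!global_ok) {
    flag[] <- "collinear"
  } else {
    if (any(complete)) {
      V <- chol2inv(chol(crossprod(X)))
      H <- X %*% V                       # n x p
      Y <- pct[complete, , drop = FALSE]
      B <- Y %*% H                       # loci x p
      fitted <- B %*% t(X)
      rss <- rowSums((Y - fitted)^2)
      df <- n - p_terms
      sigma2 <- rss / df
      b <- B[, age_col]
      s <- sqrt(sigma2 * V[age_col, age_col])
      tv <- b / s
      beta[complete] <- b
      se[complete] <- s
      tval[complete] <- tv
      pval[complete] <- 2 * pt(-abs(tv), df)
      n_used[complete] <- n
    }
    # loci with missing entries: per-locus refit on observed samples
    partial <- which(n_obs < n & !zero_var & !too_few)
    for (j in partial) {
      obs <- !is.na(pct[j, ])
      Xj <- X[obs, , drop = FALSE]
      qrj <- qr(Xj)
      if (qrj$rank < p_terms) { flag[j] <- "collinear"; next }
      fit <- stats::lm.fit(Xj, pct[j, obs])
      dfj <- sum(obs) - p_terms
      if (dfj < 1L) { flag[j] <- "insufficient_data"; next }
      rssj <- sum(fit$residuals^2)
      Vj <- chol2inv(chol(crossprod(Xj)))
      sj <- sqrt(rssj / dfj * Vj[age_col, age_col])
      beta[j] <- fit$coefficients[age_col]
      se[j] <- sj
      tval[j] <- beta[j] / sj
      pval[j] <- 2 * pt(-abs(tval[j]), dfj)
      n_used[j] <- sum(obs)
    }
  }
  flag[zero_var] <- "zero_variance"
  flag[too_few & !zero_var] <- "insufficient_data"
  n_used[flag != "ok"] <- n_obs[flag != "ok"]
  beta[flag != "ok"] <- se[flag != "ok"] <- NA_real_
  tval[flag != "ok"] <- pval[flag != "ok"] <- NA_real_

  out <- data.frame(beta_age = beta, se = se, t_value = tval,
                    p_value = pval, q_value = bh_adjust(pval),
                    n_used = n_used, flag = flag,
                    significant = !is.na(pval) & pval < alpha)
  if (!is.null(loci)) out <- cbind(loci[, c("chrom", "pos")], out)
  structure(out, class = c("admp_fit", "data.frame"),
            alpha = alpha, covariates = covariates, n_samples = n)
}

# random-intercept variant; one lmer fit per locus (small inputs only)
fit_admp_mixed <- function(pct, samples, covariates, alpha, loci,
                           random) {
  if (!requireNamespace("lmerTest", quietly = TRUE))
    stop("the random-intercept mode needs the lmerTest package",
         call. = FALSE)
  stopifnot_cols(samples, random, "samples")
  form <- stats::as.formula(paste(
    "y ~ age", if (length(covariates))
      paste("+", paste(covariates, collapse = " + ")) else "",
    sprintf("+ (1 | %s)", random)))
  J <- nrow(pct)
  res <- matrix(NA_real_, J, 4L)
  n_used <- integer(J); flag <- rep("ok", J)
  for (j in seq_len(J)) {
    obs <- !is.na(pct[j, ])
    d <- cbind(y = pct[j, obs], samples[obs, , drop = FALSE])
    if (stats::var(d$y) == 0) { flag[j] <- "zero_variance"; next }
    fit <- try(suppressMessages(suppressWarnings(
      lmerTest::lmer(form, data = d))), silent = TRUE)
    if (inherits(fit, "try-error")) { flag[j] <- "fit_failed"; next }
    cf <- stats::coef(summary(fit))
    res[j, ] <- cf["age", c("Estimate", "Std. Error", "t value",
                            "Pr(>|t|)")]
    n_used[j] <- sum(obs)
  }
  out <- data.frame(beta_age = res[, 1L], se = res[, 2L],
                    t_value = res[, 3L], p_value = res[, 4L],
                    q_value = bh_adjust(res[, 4L]), n_used = n_used,
                    flag = flag,
                    significant = !is.na(res[, 4L]) & res[, 4L] < alpha)
  if (!is.null(loci)) out <- cbind(loci[, c("chrom", "pos")], out)
  structure(out, class = c("admp_fit", "data.frame"),
            alpha = alpha, covariates = covariates,
            n_samples = nrow(samples))
}

#' @export
print.admp_fit <- function(x, ...) {
  tested <- sum(x$flag == "ok")
  cat(sprintf(
    "aDMP regression: %d loci (%d tested, %d flagged), %d samples\n",
    nrow(x), tested, nrow(x) - tested, attr(x, "n_samples")))
  cat(sprintf("  covariates: %s\n",
              paste(attr(x, "covariates"), collapse = ", ") %||% "none"))
  cat(sprintf("  significant at p < %.3g: %d (q < 0.05: %d)\n",
              attr(x, "alpha"), sum(x$significant),
              sum(x$q_value < 0.05, na.rm = TRUE)))
  invisible(x)
}

#' @method summary admp_fit
#' @export
summary.admp_fit <- function(object, ...) {
  print(object)
  sig <- object[which(object$significant), , drop = FALSE]
  if (nrow(sig)) {
    cat(sprintf("  hypermethylating with age: %d; hypomethylating: %d\n",
                sum(sig$beta_age > 0), sum(sig$beta_age < 0)))
    cat(sprintf("  median |beta_age| among significant: %.3g %%/year\n",
                stats::median(abs(sig$beta_age))))
  }
  invisible(object)
}

#' Write an aDMP table as TSV
#' @param fit an `admp_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_admp <- function(fit, path) {
  write.table(as.data.frame(fit), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
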