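## Cohort-level sexual-dimorphism statistics: the dimorphism index on group
## means, a test-dispatch rule driven by Shapiro-Wilk normality and Levene
## homoscedasticity checks, correlation screening, the multivariate
## assumption battery used before discriminant analysis, and an intraclass
## correlation for repeat-reconstruction agreement.

#' Sexual dimorphism index
#'
#' `SDI = (Xm - Xf) / (Xm + Xf) * 100` on group means, in percent. Positive
#' when the male mean is larger. Antisymmetric under swapping the sexes and
#' invariant to rescaling both means by the same factor.
#'
#' @param male_mean,female_mean positive group means.
#' @return Signed percent.
#' @examples
#' sdi(0.256, 0.289)  # -6.055: females larger
#' @export
sdi <- function(male_mean, female_mean) {
  s <- male_mean + female_mean
  if (any(!is.finite(s)) || any(s <= 0))
    stop_osteo("male_mean + female_mean must be positive", "osteo_format_error")
  (male_mean - female_mean) / s * 100
}

check_cohort <- function(cohort, variables = NULL) {
  if (inherits(cohort, "bone_record")) cohort <- as.data.frame(cohort)
  stopifnot(is.data.frame(cohort))
  if (!"sex" %in% names(cohort))
    stop_osteo("cohort must have a `sex` column", "osteo_format_error")
  if (!is.null(variables)) {
    miss <- setdiff(variables, names(cohort))
    if (length(miss))
      stop_osteo(paste("cohort lacks variable(s):", paste(miss, collapse = ", ")),
                 "osteo_format_error")
  }
  cohort
}

#' Between-sex comparison with automatic test dispatch
#'
#' Runs Shapiro-Wilk normality checks per sex and Levene's test (centered on
#' the mean) across sexes, then dispatches: both groups normal and
#' homoscedastic gives the pooled-variance t test; normal but heteroscedastic
#' gives Welch's test; non-normality in either group gives the Mann-Whitney
#' U test. The full audit trail of the dispatch is returned.
#'
#' @param cohort data frame with a `sex` column (`"male"`/`"female"`).
#' @param variable name of the numeric column to compare.
#' @param alpha significance level driving the dispatch (default 0.05).
#' @return An object of class `sex_comparison`: `test_used` (one of `"t"`,
#'   `"welch"`, `"mann_whitney"`), `statistic`, `dof`, `p_value`, and the
#'   `shapiro_p` / `levene_p` values that drove the choice.
#' @export
compare_sexes <- function(cohort, variable, alpha = 0.05) {
  cohort <- check_cohort(cohort, variable)
  x <- cohort[[variable]][cohort$sex == "male"]
  y <- cohort[[variable]][cohort$sex == "female"]
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 3L || length(y) < 3L)
    stop_osteo("need at least 3 records per sex", "osteo_format_error")
  sw <- c(male = shapiro.test(x)$p.value, female = shapiro.test(y)$p.value)
  lev <- car::leveneTest(c(x, y),
                         factor(rep(c("m", "f"), c(length(x), length(y)))),
                         center = mean)
  lev_p <- lev[["Pr(>F)"]][1]
  if (all(sw > alpha)) {
    if (lev_p > alpha) {
      ht <- t.test(x, y, var.equal = TRUE)
      used <- "t"
    } else {
      ht <- t.test(x, y, var.equal = FALSE)
      used <- "welch"
    }
    stat <- unname(ht$statistic); dof <- unname(ht$parameter)
  } else {
    ht <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
    used <- "mann_whitney"
    stat <- unname(ht$statistic); dof <- NA_real_
  }
  structure(list(variable = variable, test_used = used, statistic = stat,
                 dof = dof, p_value = ht$p.value, shapiro_p = sw,
                 levene_p = lev_p, alpha = alpha,
                 n = c(male = length(x), female = length(y)),
                 means = c(male = mean(x), female = mean(y))),
            class = "sex_comparison")
}

#' @export
print.sex_comparison <- function(x, ...) {
  cat(sprintf("<sex_comparison> %s: %s test, statistic %.4g, p = %.4g\n",
              x$variable, x$test_used, x$statistic, x$p_value))
  cat(sprintf("  dispatch: Shapiro p (m/f) %.3g/%.3g, Levene p %.3g at alpha %.2g\n",
              x$shapiro_p[1], x$shapiro_p[2], x$levene_p, x$alpha))
  invisible(x)
}

#' Correlation screening for covariate effects and multicollinearity
#'
#' Spearman correlations between subject covariates (body height, weight)
#' and each bone variable, and the Pearson correlation matrix among the
#' bone variables with `|r| > threshold` flagged as multicollinear — the
#' exclusion rule feeding discriminant variable choice.
#'
#' @param cohort data frame of bone records, optionally with `height_cm` /
#'   `weight_kg` columns.
#' @param variables bone variables to screen (default the eight standard
#'   ones present in the cohort).
#' @param threshold absolute Pearson correlation flagged as multicollinear
#'   (default 0.80).
#' @return An object of class `correlation_screen` with `spearman` (or NULL
#'   when no covariates are present), `pearson`, `flagged` pairs, and any
#'   constant variables excluded from the matrix.
#' @export
correlation_screen <- function(cohort, variables = NULL, threshold = 0.80) {
  cohort <- check_cohort(cohort)
  variables <- variables %||% intersect(BONE_VARIABLES, names(cohort))
  cohort <- check_cohort(cohort, variables)
  constant <- variables[vapply(variables, function(v)
    sd(cohort[[v]], na.rm = TRUE) == 0, logical(1))]
  active <- setdiff(variables, constant)
  pe <- cor(cohort[active], use = "pairwise.complete.obs", method = "pearson")
  ut <- which(upper.tri(pe) & abs(pe) > threshold, arr.ind = TRUE)
  flagged <- if (nrow(ut)) data.frame(var1 = rownames(pe)[ut[, 1]],
                                      var2 = colnames(pe)[ut[, 2]],
                                      r = pe[ut], row.names = NULL)
    else data.frame(var1 = character(), var2 = character(), r = numeric())
  covars <- intersect(c("height_cm", "weight_kg"), names(cohort))
  sp <- if (length(covars)) {
    out <- sapply(covars, function(cv) sapply(active, function(v)
      suppressWarnings(cor(cohort[[cv]], cohort[[v]], use = "complete.obs",
                           method = "spearman"))))
    matrix(out, nrow = length(active), dimnames = list(active, covars))
  } else NULL
  structure(list(pearson = pe, flagged = flagged, spearman = sp,
                 constant = constant, threshold = threshold),
            class = "correlation_screen")
}

#' @export
print.correlation_screen <- function(x, ...) {
  cat(sprintf("<correlation_screen> %d variables, threshold |r| > %.2f\n",
              ncol(x$pearson), x$threshold))
  if (nrow(x$flagged)) {
    cat("  multicollinear pairs:\n")
    print(x$flagged)
  } else cat("  no multicollinear pairs\n")
  if (length(x$constant))
    cat("  constant (excluded):", paste(x$constant, collapse = ", "), "\n")
  invisible(x)
}

## Mardia's multivariate skewness and kurtosis with their asymptotic tests.
mardia_test <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  Xc <- sweep(X, 2L, colMeans(X))
  S <- crossprod(Xc) / n  # ML covariance, the convention for these statistics
  if (rcond(S) < 1e-12)
    stop_osteo(paste("singular covariance among:",
                     paste(colnames(X), collapse = ", "),
                     "- drop collinear variables"),
               "osteo_singular_error")
  Sinv <- solve(S)
  G <- Xc %*% Sinv %*% t(Xc)
  b1 <- sum(G^3) / n^2
  b2 <- mean(diag(G)^2)
  skew_stat <- n * b1 / 6
  skew_df <- p * (p + 1) * (p + 2) / 6
  kurt_z <- (b2 - p * (p + 2)) * sqrt(n / (8 * p * (p + 2)))
  list(b1 = b1, b2 = b2,
       skew_stat = skew_stat, skew_df = skew_df,
       skew_p = pchisq(skew_stat, skew_df, lower.tail = FALSE),
       kurt_z = kurt_z, kurt_p = 2 * pnorm(-abs(kurt_z)))
}

## Box's M for homogeneity of covariance matrices, chi-square approximation.
box_m_test <- function(X, group) {
  X <- as.matrix(X)
  group <- factor(group)
  g <- nlevels(group); p <- ncol(X); n <- nrow(X)
  ni <- tabulate(group)
  if (any(ni <= p))
    stop_osteo("each group needs more records than variables for Box's M",
               "osteo_format_error")
  covs <- lapply(levels(group), function(l) cov(X[group == l, , drop = FALSE]))
  Sp <- Reduce(`+`, Map(function(S, k) (k - 1) * S, covs, ni)) / (n - g)
  logdets <- vapply(covs, function(S) {
    d <- determinant(S, logarithm = TRUE)
    if (d$sign <= 0) stop_osteo(
      "singular within-group covariance; drop collinear variables",
      "osteo_singular_error")
    as.numeric(d$modulus)
  }, numeric(1))
  dp <- determinant(Sp, logarithm = TRUE)
  if (dp$sign <= 0)
    stop_osteo("singular pooled covariance; drop collinear variables",
               "osteo_singular_error")
  M <- (n - g) * as.numeric(dp$modulus) - sum((ni - 1) * logdets)
  c1 <- (sum(1 / (ni - 1)) - 1 / (n - g)) *
    (2 * p^2 + 3 * p - 1) / (6 * (p + 1) * (g - 1))
  stat <- M * (1 - c1)
  df <- p * (p + 1) * (g - 1) / 2
  list(M = M, stat = stat, df = df,
       p = pchisq(stat, df, lower.tail = FALSE))
}

#' Multivariate assumption battery for discriminant analysis
#'
#' Per-sex Mardia skewness/kurtosis tests of multivariate normality,
#' per-record Mahalanobis distances (within each sex, against its own
#' covariance) with chi-square outlier probabilities, and Box's M test of
#' covariance homogeneity. A record is a multivariate outlier when its
#' chi-square tail probability falls below `outlier_alpha`, and Box's M
#' passes when its p-value exceeds `boxm_alpha` (both default 0.001).
#'
#' @param cohort data frame with a `sex` column.
#' @param variables variables entering the battery.
#' @param outlier_alpha Mahalanobis outlier threshold (default 0.001).
#' @param boxm_alpha Box's M pass threshold (default 0.001).
#' @return An object of class `assumption_battery`: `mardia` (per sex),
#'   `mahalanobis` (data frame with distances, p-values and outlier flags),
#'   `box_m`, and the thresholds used.
#' @export
assumption_battery <- function(cohort, variables = NULL,
                               outlier_alpha = 0.001, boxm_alpha = 0.001) {
  cohort <- check_cohort(cohort)
  variables <- variables %||% intersect(BONE_VARIABLES, names(cohort))
  cohort <- check_cohort(cohort, variables)
  cohort <- cohort[complete.cases(cohort[variables]), , drop = FALSE]
  sexes <- unique(cohort$sex)
  if (length(sexes) < 2L)
    stop_osteo("both sexes must be present", "osteo_format_error")
  p <- length(variables)
  for (s in sexes)
    if (sum(cohort$sex == s) <= p)
      stop_osteo("each group needs more records than variables",
                 "osteo_format_error")
  mardia <- lapply(setNames(sexes, sexes), function(s)
    mardia_test(cohort[cohort$sex == s, variables]))
  md <- do.call(rbind, lapply(sexes, function(s) {
    Xg <- as.matrix(cohort[cohort$sex == s, variables])
    S <- cov(Xg)
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 1e-12)
      stop_osteo(paste("singular covariance among:",
                       paste(variables, collapse = ", ")),
                 "osteo_singular_error")
    d2 <- mahalanobis(Xg, colMeans(Xg), S)
    data.frame(row = which(cohort$sex == s), sex = s, d2 = d2,
               p = pchisq(d2, df = p, lower.tail = FALSE))
  }))
  md$outlier <- md$p < outlier_alpha
  md <- md[order(md$row), , drop = FALSE]
  bm <- box_m_test(cohort[variables], cohort$sex)
  structure(list(mardia = mardia, mahalanobis = md, box_m = bm,
                 variables = variables, outlier_alpha = outlier_alpha,
                 boxm_alpha = boxm_alpha,
                 box_m_pass = bm$p > boxm_alpha),
            class = "assumption_battery")
}

#' @export
print.assumption_battery <- function(x, ...) {
  cat(sprintf("<assumption_battery> %d variables\n", length(x$variables)))
  for (s in names(x$mardia)) {
    m <- x$mardia[[s]]
    cat(sprintf("  Mardia (%s): skewness p = %.3g, kurtosis p = %.3g\n",
                s, m$skew_p, m$kurt_p))
  }
  cat(sprintf("  Mahalanobis outliers (p < %g): %d\n", x$outlier_alpha,
              sum(x$mahalanobis$outlier)))
  cat(sprintf("  Box's M = %.4g, chi-square %.4g (df %g), p = %.3g [%s]\n",
              x$box_m$M, x$box_m$stat, x$box_m$df, x$box_m$p,
              if (x$box_m_pass) "pass" else "fail"))
  invisible(x)
}

#' Intraclass correlation for paired repeat measurements
#'
#' Two-way mixed-effects, absolute-agreement, single-measurement ICC —
#' the form suited to two repeat scan/reconstruction passes over the same
#' bones, where the "raters" are the two reconstruction runs.
#'
#' @param measurements_a,measurements_b paired numeric vectors (same bones,
#'   two measurement passes), length >= 3.
#' @return An object of class `icc_result` with `icc`, the mean squares and
#'   the design sizes.
#' @export
icc_agreement <- function(measurements_a, measurements_b) {
  a <- as.numeric(measurements_a); b <- as.numeric(measurements_b)
  if (length(a) != length(b) || length(a) < 3L)
    stop_osteo("need equal-length paired vectors with n >= 3",
               "osteo_format_error")
  n <- length(a); k <- 2L
  Y <- cbind(a, b)
  row_means <- rowMeans(Y)
  if (sd(row_means) < .Machine$double.eps^0.5 * (abs(mean(row_means)) + 1))
    stop_osteo("zero between-subject variance: ICC undefined",
               "osteo_degenerate_error")
  col_means <- colMeans(Y)
  grand <- mean(Y)
  SSR <- k * sum((row_means - grand)^2)
  SSC <- n * sum((col_means - grand)^2)
  SST <- sum((Y - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k / n * (MSC - MSE))
  structure(list(icc = icc, MSR = MSR, MSC = MSC, MSE = MSE, n = n, k = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC(A,1) = %.4f (n = %d subjects, k = %d raters)\n",
              x$icc, x$n, x$k))
  invisible(x)
}
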