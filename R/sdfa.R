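## Two-group canonical discriminant analysis with stepwise Wilks'-lambda
## variable selection. The canonical direction is the Fisher discriminant
## (pooled within-group covariance inverse times the mean difference), scaled
## so the pooled within-group score variance is one and shifted so the
## overall (case-weighted) mean score is zero; group centroids are the scores
## of the group mean vectors and the equal-priors sectioning point is their
## midpoint.

## Within- and total-group SSCP matrices for a variable subset.
sscp_matrices <- function(X, group) {
  Xc_t <- sweep(X, 2L, colMeans(X))
  Tm <- crossprod(Xc_t)
  W <- matrix(0, ncol(X), ncol(X))
  for (l in levels(group)) {
    Xg <- X[group == l, , drop = FALSE]
    W <- W + crossprod(sweep(Xg, 2L, colMeans(Xg)))
  }
  list(W = W, T = Tm)
}

#' Wilks' lambda for a two-group variable subset
#'
#' `Lambda = det(W) / det(T)` with W and T the within-group and total SSCP
#' matrices. Values near 0 indicate strong group separation; 1 means none.
#'
#' @param data data frame containing `variables` and the grouping column.
#' @param variables character vector of variable names (empty gives 1).
#' @param group name of the two-level grouping column (default `"sex"`).
#' @return Wilks' lambda in (0, 1].
#' @export
wilks_lambda <- function(data, variables, group = "sex") {
  if (length(variables) == 0L) return(1)
  g <- droplevels(factor(data[[group]]))
  X <- as.matrix(data[variables])
  m <- sscp_matrices(X, g)
  dW <- determinant(m$W, logarithm = TRUE)
  dT <- determinant(m$T, logarithm = TRUE)
  if (dW$sign <= 0 || dT$sign <= 0)
    stop_osteo(paste("singular SSCP matrix for variables:",
                     paste(variables, collapse = ", ")),
               "osteo_singular_error")
  exp(as.numeric(dW$modulus) - as.numeric(dT$modulus))
}

## Partial F for moving between nested subsets: `p` is the size of the
## smaller model (the one the tested variable is NOT in), g the number of
## groups. F = ((L_small / L_large) - 1) * (n - g - p) / (g - 1), with
## df1 = g - 1 and df2 = n - g - p. For p = 0, g = 2 this reduces to the
## one-way ANOVA F with (1, n - 2) df.
partial_f <- function(lambda_small, lambda_large, n, p, g = 2L) {
  (lambda_small / lambda_large - 1) * (n - g - p) / (g - 1)
}

#' Stepwise variable selection by Wilks' lambda
#'
#' At each step the candidate that minimizes the overall Wilks' lambda is
#' entered if its partial F-to-enter reaches `f_enter`; after every entry,
#' included variables whose partial F-to-remove falls below `f_remove` are
#' removed (smallest first). Iterates to a fixed point. An empty selection
#' (no candidate passes the entry gate) is a valid result, not an error.
#'
#' @param data data frame with the candidate columns and the grouping column.
#' @param candidates character vector of candidate variable names.
#' @param group two-level grouping column name (default `"sex"`).
#' @param f_enter minimum partial F to enter (default 3.84).
#' @param f_remove maximum partial F to remove (default 2.71); must be below
#'   `f_enter`.
#' @param max_steps safety cap on entry/removal steps.
#' @return List with `selected` (ordered names) and `trace` (a data frame
#'   with one row per action: step, action, variable, lambda, partial F).
#' @export
stepwise_select <- function(data, candidates, group = "sex",
                            f_enter = 3.84, f_remove = 2.71,
                            max_steps = 4L * length(candidates) + 4L) {
  if (!(f_enter > f_remove) || f_remove < 0)
    stop_osteo("need f_enter > f_remove >= 0", "osteo_format_error")
  g <- droplevels(factor(data[[group]]))
  if (nlevels(g) != 2L)
    stop_osteo("grouping column must have exactly two levels", "osteo_format_error")
  n <- nrow(data)
  current <- character(0)
  lambda_cur <- 1
  trace <- list()
  seen <- character(0)
  step <- 0L
  repeat {
    changed <- FALSE
    ## entry scan
    pool <- setdiff(candidates, current)
    if (length(pool)) {
      lam <- vapply(pool, function(v)
        tryCatch(wilks_lambda(data, c(current, v), group),
                 osteo_singular_error = function(e) NA_real_), numeric(1))
      ok <- which(is.finite(lam))
      if (length(ok)) {
        best <- ok[which.min(lam[ok])]
        Fe <- partial_f(lambda_cur, lam[best], n, length(current))
        if (is.finite(Fe) && Fe >= f_enter) {
          current <- c(current, pool[best])
          lambda_cur <- lam[best]
          step <- step + 1L
          trace[[length(trace) + 1L]] <- data.frame(
            step = step, action = "enter", variable = pool[best],
            lambda = lambda_cur, partial_f = Fe)
          changed <- TRUE
        }
      }
    }
    ## removal scan (after an entry, or to settle the final model)
    repeat {
      if (length(current) == 0L) break
      Fr <- vapply(current, function(v) {
        lam_wo <- wilks_lambda(data, setdiff(current, v), group)
        partial_f(lam_wo, lambda_cur, n, length(current) - 1L)
      }, numeric(1))
      worst <- which.min(Fr)
      if (length(worst) && Fr[worst] < f_remove) {
        vic <- current[worst]
        current <- setdiff(current, vic)
        lambda_cur <- wilks_lambda(data, current, group)
        step <- step + 1L
        trace[[length(trace) + 1L]] <- data.frame(
          step = step, action = "remove", variable = vic,
          lambda = lambda_cur, partial_f = Fr[worst])
        changed <- TRUE
      } else break
    }
    state <- paste(sort(current), collapse = "+")
    if (!changed || step >= max_steps || state %in% seen) break
    seen <- c(seen, state)
  }
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(step = integer(), action = character(), variable = character(),
               lambda = numeric(), partial_f = numeric())
  list(selected = current, trace = trace)
}

#' Fit a two-group stepwise discriminant function
#'
#' The classic fitting interface: `sdfa(sex ~ sa_v + Hn + density, cohort)`.
#' With `stepwise = TRUE` (default) the right-hand-side variables are the
#' candidate pool and the model is selected by [stepwise_select()] under the
#' partial-F gates; with `stepwise = FALSE` all of them enter. The fitted
#' object carries unstandardized and standardized coefficients, the
#' structure matrix (pooled within-group correlations between variables and
#' the discriminant score), group centroids, the equal-priors sectioning
#' point, Wilks' lambda and its Bartlett chi-square test
#' (`-(n - 1 - (p + g)/2) log(Lambda)` on `p` degrees of freedom).
#'
#' The overall sign of a canonical axis is arbitrary; fitted models are
#' oriented so the variable with the largest absolute standardized
#' coefficient has a positive coefficient. Classification is invariant to
#' this convention.
#'
#' @param formula `group ~ var1 + var2 + ...`; use `.` for all numeric
#'   columns.
#' @param data data frame; the grouping column must have exactly two levels
#'   (for sex cohorts, `male` and `female`).
#' @param stepwise select variables by partial-F gated Wilks' lambda
#'   (default `TRUE`).
#' @param f_enter,f_remove partial-F gates (defaults 3.84 / 2.71).
#' @param priors group prior probabilities for the sectioning point; the
#'   default `"equal"` uses equal priors (midpoint rule).
#' @return An object of class `sdfa`; see Details. An empty selection under
#'   `stepwise = TRUE` returns an `sdfa` object with zero variables, for
#'   which `predict()` declines to classify.
#' @seealso [predict.sdfa()], [loo_accuracy()], [published_functions()]
#' @examples
#' set.seed(1)
#' d <- data.frame(sex = rep(c("male", "female"), each = 30),
#'                 sa_v = c(rnorm(30, 0.386, 0.018), rnorm(30, 0.450, 0.021)),
#'                 Hn = c(rnorm(30, 0.198, 0.009), rnorm(30, 0.192, 0.008)))
#' fit <- sdfa(sex ~ sa_v + Hn, d)
#' fit
#' table(predict(fit, d), d$sex)
#' @export
sdfa <- function(formula, data, stepwise = TRUE, f_enter = 3.84,
                 f_remove = 2.71, priors = "equal") {
  stopifnot(inherits(formula, "formula"), is.data.frame(data))
  group <- all.vars(formula[[2]])
  rhs <- attr(stats::terms(formula, data = data), "term.labels")
  data <- data[complete.cases(data[c(group, rhs)]), , drop = FALSE]
  glev <- droplevels(factor(data[[group]]))
  if (nlevels(glev) != 2L)
    stop_osteo("grouping column must have exactly two levels", "osteo_format_error")
  ## sex cohorts conventionally list the male group first
  if (all(c("male", "female") %in% levels(glev)))
    glev <- factor(glev, levels = c("male", "female"))
  selection <- NULL
  if (stepwise) {
    selection <- stepwise_select(data, rhs, group, f_enter, f_remove)
    variables <- selection$selected
  } else variables <- rhs
  fit <- fit_discriminant_core(data, variables, group, glev, priors)
  fit$selection <- selection
  fit$call <- match.call()
  fit
}

fit_discriminant_core <- function(data, variables, group, glev, priors = "equal") {
  n <- nrow(data)
  lev <- levels(glev)
  ni <- tabulate(glev)
  if (length(variables) == 0L) {
    out <- structure(list(variables = character(0), coefficients = numeric(0),
                          constant = NA_real_, group = group, levels = lev,
                          n = setNames(ni, lev), fitted = TRUE,
                          wilks_lambda = 1), class = "sdfa")
    return(out)
  }
  if (any(ni < 2L))
    stop_osteo("need at least 2 records per group", "osteo_format_error")
  X <- as.matrix(data[variables])
  m <- sscp_matrices(X, glev)
  Sp <- m$W / (n - 2L)
  if (min(eigen(Sp, symmetric = TRUE, only.values = TRUE)$values) <= 1e-12)
    stop_osteo(paste("singular pooled covariance among:",
                     paste(variables, collapse = ", ")),
               "osteo_singular_error")
  mean1 <- colMeans(X[glev == lev[1], , drop = FALSE])
  mean2 <- colMeans(X[glev == lev[2], , drop = FALSE])
  w <- solve(Sp, mean1 - mean2)
  a <- w / sqrt(sum(w * (Sp %*% w)))        # pooled within-group score var = 1
  std <- a * sqrt(diag(Sp))
  if (std[which.max(abs(std))] < 0) { a <- -a; std <- -std }
  const <- -sum(a * colMeans(X))            # overall mean score = 0
  centroids <- setNames(c(sum(a * mean1) + const, sum(a * mean2) + const), lev)
  structure_mat <- as.numeric(Sp %*% a) / sqrt(diag(Sp))
  names(structure_mat) <- variables
  lambda <- wilks_lambda(data, variables, group)
  p <- length(variables)
  chi <- -(n - 1 - (p + 2) / 2) * log(lambda)
  sp_point <- sectioning_point(centroids[[1]], centroids[[2]], priors)
  structure(list(variables = variables,
                 coefficients = setNames(as.numeric(a), variables),
                 constant = const,
                 std_coefficients = setNames(as.numeric(std), variables),
                 structure_matrix = structure_mat,
                 centroids = centroids,
                 sectioning_point = sp_point,
                 wilks_lambda = lambda, chi_square = chi, chi_df = p,
                 p_value = pchisq(chi, p, lower.tail = FALSE),
                 group = group, levels = lev, n = setNames(ni, lev),
                 group_means = rbind(mean1, mean2),
                 fitted = TRUE,
                 model_frame = data[c(group, variables)]),
            class = "sdfa")
}

#' Sectioning point between two group centroids
#'
#' Under equal priors the classification threshold on the discriminant score
#' is the centroid midpoint; unequal priors shift it by
#' `log(p2/p1) / (c1 - c2)` (the normal-theory cutoff for unit within-group
#' variance).
#'
#' @param centroid_a,centroid_b group centroids (distinct).
#' @param priors `"equal"` or a length-2 numeric vector of priors for groups
#'   a and b.
#' @return The threshold score.
#' @examples
#' sectioning_point(1.554, -1.503)  # 0.0255
#' @export
sectioning_point <- function(centroid_a, centroid_b, priors = "equal") {
  if (!is.finite(centroid_a) || !is.finite(centroid_b) ||
      centroid_a == centroid_b)
    stop_osteo("centroids must be distinct", "osteo_degenerate_error")
  mid <- (centroid_a + centroid_b) / 2
  if (identical(priors, "equal")) return(mid)
  priors <- priors / sum(priors)
  mid + log(priors[2] / priors[1]) / (centroid_a - centroid_b)
}

#' Discriminant scores and classification
#'
#' `type = "score"` returns `Y = a_1 x_1 + ... + a_n x_n + C`;
#' `type = "class"` compares Y with the sectioning point and returns the
#' group on the matching side (the side of each group's centroid). Scores
#' exactly at the sectioning point classify as `"indeterminate"`.
#'
#' @param object an `sdfa` model (fitted or from [published_functions()]).
#' @param newdata data frame (or named list/vector) containing the model
#'   variables.
#' @param type `"class"` (default) or `"score"`.
#' @param ... unused.
#' @return Numeric scores or a character vector of group labels.
#' @export
predict.sdfa <- function(object, newdata = NULL,
                         type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (is.null(object$model_frame))
      stop_osteo("no stored data; supply `newdata`", "osteo_format_error")
    newdata <- object$model_frame
  }
  if (!is.data.frame(newdata)) newdata <- as.data.frame(as.list(newdata))
  if (length(object$variables) == 0L)
    stop_osteo("empty model (no variables passed the entry gate); cannot score",
               "osteo_format_error")
  miss <- setdiff(object$variables, names(newdata))
  if (length(miss))
    stop_osteo(paste("record lacks model variable(s):",
                     paste(miss, collapse = ", ")), "osteo_format_error")
  X <- as.matrix(newdata[object$variables])
  y <- as.numeric(X %*% object$coefficients) + object$constant
  if (type == "score") return(y)
  sp <- object$sectioning_point
  first_above <- object$centroids[[1]] > sp
  out <- ifelse(y == sp, "indeterminate",
                ifelse((y > sp) == first_above, object$levels[1],
                       object$levels[2]))
  out
}

#' @rdname predict.sdfa
#' @export
discriminant_score <- function(object, newdata) {
  predict(object, newdata, type = "score")
}

#' @rdname predict.sdfa
#' @export
classify_sex <- function(object, newdata) {
  predict(object, newdata, type = "class")
}

#' @export
coef.sdfa <- function(object, ...) {
  c(object$coefficients, `(constant)` = object$constant)
}

#' @export
print.sdfa <- function(x, ...) {
  src <- if (isTRUE(x$fitted)) "fitted" else
    sprintf("published (%s MT%d)", x$side, x$metatarsal)
  cat(sprintf("<sdfa> %s two-group discriminant function\n", src))
  if (length(x$variables) == 0L) {
    cat("  empty model: no variable passed the entry gate\n")
    return(invisible(x))
  }
  cat("  Y =", paste(sprintf("%+.4g*%s", x$coefficients, x$variables),
                     collapse = " "),
      sprintf("%+.4g\n", x$constant))
  cat(sprintf("  Wilks' lambda %.4g", x$wilks_lambda))
  if (!is.null(x$chi_square))
    cat(sprintf(", chi-square %.4g (df %d), p = %.3g", x$chi_square,
                x$chi_df, x$p_value))
  cat("\n")
  cat(sprintf("  centroids: %s = %.4g, %s = %.4g; sectioning point %.4g\n",
              x$levels[1], x$centroids[[1]], x$levels[2], x$centroids[[2]],
              x$sectioning_point))
  invisible(x)
}

#' @export
summary.sdfa <- function(object, ...) {
  print(object)
  if (length(object$variables)) {
    tab <- data.frame(coefficient = object$coefficients,
                      standardized = object$std_coefficients %||% NA,
                      structure = object$structure_matrix %||% NA)
    cat("\nVariables:\n")
    print(round(tab, 4))
  }
  if (!is.null(object$selection) && nrow(object$selection$trace)) {
    cat("\nStepwise trace:\n")
    print(object$selection$trace, row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.sdfa <- function(x, ...) {
  if (is.null(x$model_frame))
    stop_osteo("plot needs a fitted model with stored data", "osteo_format_error")
  y <- predict(x, type = "score")
  g <- factor(x$model_frame[[x$group]], levels = x$levels)
  br <- pretty(range(y), 20)
  h1 <- hist(y[g == x$levels[1]], breaks = br, plot = FALSE)
  h2 <- hist(y[g == x$levels[2]], breaks = br, plot = FALSE)
  ylim <- c(0, max(h1$counts, h2$counts))
  plot(h1, col = grDevices::adjustcolor("steelblue", 0.5), ylim = ylim,
       main = "Discriminant scores", xlab = "Y", ...)
  plot(h2, col = grDevices::adjustcolor("indianred", 0.5), add = TRUE)
  abline(v = x$sectioning_point, lty = 2)
  abline(v = x$centroids, lty = 3)
  graphics::legend("topright", fill = grDevices::adjustcolor(
    c("steelblue", "indianred"), 0.5), legend = x$levels, bty = "n")
  invisible(x)
}

#' Leave-one-out classification report
#'
#' Classifies every record twice: with the function fitted on the full
#' sample (original block) and with the function refitted on all other
#' records (cross-validated block). The variable set stays fixed across
#' leave-one-out refits — only the coefficients are re-estimated — unless
#' `reselect = TRUE` repeats the stepwise selection inside every fold.
#'
#' @param x an `sdfa` fitted with stored data, or a data frame.
#' @param variables variable names (required when `x` is a data frame;
#'   defaults to the model's variables otherwise).
#' @param group grouping column name (default the model's, or `"sex"`).
#' @param reselect rerun stepwise selection in each fold (default `FALSE`).
#' @param f_enter,f_remove gates used when `reselect = TRUE`.
#' @return An object of class `classification_report`: per-group and total
#'   counts and percentages for the original and cross-validated blocks.
#' @export
loo_accuracy <- function(x, variables = NULL, group = NULL, reselect = FALSE,
                         f_enter = 3.84, f_remove = 2.71) {
  if (inherits(x, "sdfa")) {
    data <- x$model_frame
    variables <- variables %||% x$variables
    group <- group %||% x$group
  } else {
    data <- x
    group <- group %||% "sex"
    if (is.null(variables))
      stop_osteo("supply `variables` when x is a data frame", "osteo_format_error")
  }
  data <- data[complete.cases(data[c(group, variables)]), , drop = FALSE]
  glev <- droplevels(factor(data[[group]]))
  if (all(c("male", "female") %in% levels(glev)))
    glev <- factor(glev, levels = c("male", "female"))
  if (any(tabulate(glev) < 2L))
    stop_osteo("need at least 2 records per group", "osteo_format_error")
  full <- fit_discriminant_core(data, variables, group, glev)
  orig <- predict(full, data)
  n <- nrow(data)
  cv <- character(n)
  for (i in seq_len(n)) {
    gi <- droplevels(glev[-i])
    if (nlevels(gi) != 2L)
      stop_osteo("leave-one-out fold lost a group; need more records",
                 "osteo_format_error")
    vars_i <- variables
    if (reselect)
      vars_i <- stepwise_select(data[-i, , drop = FALSE], variables, group,
                                f_enter, f_remove)$selected
    fit_i <- fit_discriminant_core(data[-i, , drop = FALSE], vars_i, group,
                                   factor(glev[-i], levels = levels(glev)))
    cv[i] <- predict(fit_i, data[i, , drop = FALSE])
  }
  truth <- as.character(glev)
  block <- function(pred) {
    per <- t(vapply(levels(glev), function(l) {
      tot <- sum(truth == l)
      ok <- sum(truth == l & pred == l)
      c(correct = ok, total = tot, percent = 100 * ok / tot)
    }, numeric(3)))
    list(per_group = per,
         total_percent = 100 * sum(pred == truth) / length(truth))
  }
  structure(list(original = block(orig), cross_validated = block(cv),
                 variables = variables, levels = levels(glev), n = n,
                 predictions = data.frame(truth = truth, original = orig,
                                          cross_validated = cv)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %d cases, variables: %s\n", x$n,
              paste(x$variables, collapse = ", ")))
  for (blk in c("original", "cross_validated")) {
    b <- x[[blk]]
    cat(sprintf("  %s:\n", gsub("_", "-", blk)))
    for (l in rownames(b$per_group))
      cat(sprintf("    %-8s %d/%d (%.1f%%)\n", l,
                  b$per_group[l, "correct"], b$per_group[l, "total"],
                  b$per_group[l, "percent"]))
    cat(sprintf("    total    %.1f%%\n", b$total_percent))
  }
  invisible(x)
}
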