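## Cohort simulation: per-sex multivariate normal draws with the reference
## cohort's means and SDs as defaults, rejection resampling against the
## printed min/max envelopes (no probability spikes at the bounds), and
## renormalization of the linear and inertial triplets so every simulated
## record satisfies the sum-to-one constraints by construction.

#' Cohort simulation specification
#'
#' Defaults come from [mt_reference_stats()] for the chosen side and
#' metatarsal; any subset can be overridden. Variables are drawn
#' independently unless a correlation matrix is supplied (the reference
#' tables publish only marginal statistics, so independence is the neutral
#' default; simulated classification accuracies are approximate to the
#' extent real variables co-vary).
#'
#' @param side `"left"` or `"right"`.
#' @param metatarsal metatarsal index 1..5.
#' @param n_male,n_female group sizes (default 30/30, the reference design).
#' @param variables which bone variables to simulate (default all eight).
#' @param stats optional data frame in [mt_reference_stats()] layout
#'   overriding the defaults.
#' @param correlation optional common correlation matrix among `variables`
#'   (positive semi-definite, unit diagonal).
#' @param clip enforce the printed min/max by rejection resampling
#'   (default `TRUE`).
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(side = "left", metatarsal = 3L, n_male = 30L,
                        n_female = 30L, variables = bone_variables(),
                        stats = NULL, correlation = NULL, clip = TRUE) {
  st <- stats %||% mt_reference_stats(side, metatarsal)
  st <- st[st$variable %in% variables, , drop = FALSE]
  miss <- setdiff(variables, unique(st$variable))
  if (length(miss))
    stop_osteo(paste("no statistics for variable(s):",
                     paste(miss, collapse = ", ")), "osteo_format_error")
  if (any(st$sd <= 0))
    stop_osteo("SDs must be positive", "osteo_format_error")
  if (any(st$min > st$max))
    stop_osteo("infeasible clipping bounds (min > max)", "osteo_format_error")
  if (!is.null(correlation)) {
    correlation <- as.matrix(correlation)
    p <- length(variables)
    if (!all(dim(correlation) == c(p, p)) ||
        max(abs(diag(correlation) - 1)) > 1e-8 ||
        min(eigen(correlation, symmetric = TRUE,
                  only.values = TRUE)$values) < -1e-8)
      stop_osteo("correlation must be PSD with unit diagonal, matching `variables`",
                 "osteo_format_error")
  }
  structure(list(side = side, metatarsal = as.integer(metatarsal),
                 n_male = as.integer(n_male), n_female = as.integer(n_female),
                 variables = variables, stats = st,
                 correlation = correlation, clip = clip),
            class = "cohort_spec")
}

#' Simulate a cohort of bone records
#'
#' Draws per-sex multivariate normal records under `spec`, resamples any
#' record violating the min/max envelope (when `spec$clip`), then
#' renormalizes the `(Ln, Wn, Hn)` and `(pmi_x, pmi_y, pmi_z)` triplets to
#' sum to one when all three members are simulated. Optionally attaches
#' per-subject body height and weight covariates; `sa_v_height_r` induces a
#' within-sex negative association between height and SA:V through a
#' Gaussian copula on the latent normals.
#'
#' @param spec a [cohort_spec()].
#' @param seed optional integer seed.
#' @param covariates draw `height_cm` / `weight_kg` (default `FALSE`).
#' @param sa_v_height_r latent within-sex correlation between height and
#'   SA:V (default 0 = independent; the screening tests use about -0.7).
#' @return Data frame of class `cohort`: `subject_id, sex, side, metatarsal`,
#'   the simulated variables, and covariates when requested.
#' @export
simulate_cohort <- function(spec, seed = NULL, covariates = FALSE,
                            sa_v_height_r = 0) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  ## height/weight: realistic young-adult values (cm, kg); within-sex SDs
  hw <- list(male = c(h_mean = 176.6, h_sd = 5.5, w_mean = 68, w_sd = 8),
             female = c(h_mean = 163.5, h_sd = 5.2, w_mean = 55, w_sd = 6.5))
  draw_sex <- function(sex, n) {
    st <- spec$stats[spec$stats$sex == sex, , drop = FALSE]
    st <- st[match(spec$variables, st$variable), , drop = FALSE]
    p <- nrow(st)
    L <- if (is.null(spec$correlation)) diag(p) else
      chol_psd(spec$correlation)
    hz <- rnorm(n)
    draw_z <- function(m) {
      Z <- matrix(rnorm(m * p), m, p) %*% t(L)
      iv <- match("sa_v", spec$variables)
      if (!is.na(iv) && sa_v_height_r != 0)
        Z[, iv] <- sa_v_height_r * hz[seq_len(m)] +
          sqrt(1 - sa_v_height_r^2) * Z[, iv]
      Z
    }
    X <- sweep(draw_z(n) %*% diag(st$sd, p), 2L, st$mean, `+`)
    if (spec$clip) {
      for (iter in seq_len(1000L)) {
        bad <- which(rowSums(sweep(X, 2L, st$min, `<`) |
                             sweep(X, 2L, st$max, `>`)) > 0)
        if (!length(bad)) break
        ## redraw offending records wholesale (reject-and-redraw)
        Z <- matrix(rnorm(length(bad) * p), length(bad), p) %*% t(L)
        X[bad, ] <- sweep(Z %*% diag(st$sd, p), 2L, st$mean, `+`)
      }
      if (length(bad))
        stop_osteo("rejection resampling failed to satisfy the min/max bounds",
                   "osteo_format_error")
    }
    colnames(X) <- spec$variables
    out <- data.frame(sex = sex, X, stringsAsFactors = FALSE)
    if (covariates) {
      pars <- hw[[sex]]
      out$height_cm <- pars["h_mean"] + pars["h_sd"] * hz
      out$weight_kg <- rnorm(n, pars["w_mean"], pars["w_sd"]) +
        0.5 * (out$height_cm - pars["h_mean"])
    }
    out
  }
  d <- rbind(draw_sex("male", spec$n_male), draw_sex("female", spec$n_female))
  for (trip in list(c("Ln", "Wn", "Hn"), c("pmi_x", "pmi_y", "pmi_z"))) {
    if (all(trip %in% names(d))) {
      s <- rowSums(d[trip])
      d[trip] <- d[trip] / s
    }
  }
  d <- data.frame(subject_id = sprintf("sim%03d", seq_len(nrow(d))),
                  sex = d$sex, side = spec$side, metatarsal = spec$metatarsal,
                  d[setdiff(names(d), "sex")],
                  stringsAsFactors = FALSE)
  class(d) <- c("cohort", class(d))
  d
}

chol_psd <- function(S) {
  ev <- eigen(S, symmetric = TRUE)
  ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
}

COHORT_COLUMNS <- c("subject_id", "sex", "side", "metatarsal",
                    "Ln", "Wn", "Hn", "sa_v", "density",
                    "pmi_x", "pmi_y", "pmi_z", "height_cm", "weight_kg")

#' Read and write cohort CSV files
#'
#' The cohort schema is `subject_id, sex, side, metatarsal`, the eight bone
#' variables, and optional `height_cm, weight_kg`. Floats are written with
#' full precision; missing covariates are simply absent columns.
#'
#' @param path CSV path.
#' @param cohort data frame in cohort layout.
#' @return `read_cohort` returns the validated data frame; `write_cohort`
#'   returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path))
    stop_osteo(sprintf("file not found: %s", path), "osteo_io_error")
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sex")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop_osteo(paste("cohort CSV lacks column(s):", paste(miss, collapse = ", ")),
               "osteo_format_error")
  class(d) <- c("cohort", class(d))
  d
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  keep <- intersect(COHORT_COLUMNS, names(cohort))
  extra <- setdiff(names(cohort), COHORT_COLUMNS)
  write.csv(cohort[c(keep, extra)], path, row.names = FALSE)
  invisible(path)
}
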