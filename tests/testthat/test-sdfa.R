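sim_lr_cohort <- function(seed, n = 30L) {
  # left third metatarsal reference statistics, independent variables
  simulate_cohort(cohort_spec("left", 3, n_male = n, n_female = n),
                  seed = seed)
}

test_that("wilks_lambda agrees with the MANOVA oracle", {
  set.seed(2)
  d <- sim_lr_cohort(2)
  for (vars in list("sa_v", c("sa_v", "Hn"), c("sa_v", "Hn", "density"),
                    c("pmi_x", "pmi_y"))) {
    expect_equal(wilks_lambda(d, vars), oracle_wilks(d, vars),
                 tolerance = 1e-10)
  }
})

test_that("fitted discriminant satisfies its defining identities", {
  d <- sim_lr_cohort(4)
  fit <- sdfa(sex ~ sa_v + Hn + density, d, stepwise = FALSE)
  # score at group means reproduces the centroids exactly
  gm <- aggregate(d[c("sa_v", "Hn", "density")], list(sex = d$sex), mean)
  for (i in seq_len(2)) {
    y <- predict(fit, gm[i, ], type = "score")
    expect_equal(y, unname(fit$centroids[gm$sex[i]]), tolerance = 1e-12)
  }
  # pooled within-group score variance = 1
  y <- predict(fit, d, type = "score")
  g <- factor(d$sex)
  ssw <- sum(unlist(lapply(levels(g), function(l)
    (y[g == l] - mean(y[g == l]))^2)))
  expect_equal(ssw / (length(y) - 2), 1, tolerance = 1e-12)
  # equal n: centroids symmetric about the zero overall mean
  expect_equal(fit$centroids[[1]], -fit$centroids[[2]], tolerance = 1e-10)
  expect_equal(mean(y), 0, tolerance = 1e-12)
  expect_equal(fit$sectioning_point, 0, tolerance = 1e-10)
  # orientation: largest standardized coefficient is positive
  expect_gt(fit$std_coefficients[which.max(abs(fit$std_coefficients))], 0)
  # canonical direction matches MASS::lda up to scale
  l <- MASS::lda(sex ~ sa_v + Hn + density, d)
  expect_equal(unname(fit$coefficients / fit$coefficients[1]),
               unname(l$scaling[, 1] / l$scaling[1, 1]), tolerance = 1e-8)
})

test_that("univariate discriminant recovers the standardized separation", {
  set.seed(10)
  delta <- 1.7
  n <- 10000L
  d <- data.frame(sex = rep(c("male", "female"), each = n),
                  v = c(rnorm(n, delta), rnorm(n, 0)))
  fit <- sdfa(sex ~ v, d, stepwise = FALSE)
  expect_equal(abs(diff(fit$centroids)), delta, tolerance = 0.05 * delta,
               ignore_attr = TRUE)
})

test_that("classification is invariant to the canonical sign convention", {
  d <- sim_lr_cohort(12)
  fit <- sdfa(sex ~ sa_v + Hn, d, stepwise = FALSE)
  flipped <- fit
  flipped$coefficients <- -fit$coefficients
  flipped$constant <- -fit$constant
  flipped$centroids <- -fit$centroids
  flipped$sectioning_point <- -fit$sectioning_point
  expect_identical(predict(fit, d), predict(flipped, d))
  # a score exactly at the sectioning point is indeterminate (exact-integer
  # model so the tie is representable)
  toy <- structure(list(variables = "v", coefficients = c(v = 1),
                        constant = -1, centroids = c(male = 1, female = -1),
                        sectioning_point = 0, group = "sex",
                        levels = c("male", "female"), fitted = FALSE),
                   class = "sdfa")
  expect_identical(unname(predict(toy, data.frame(v = 1))), "indeterminate")
  expect_identical(unname(predict(toy, data.frame(v = 2))), "male")
  expect_identical(unname(predict(toy, data.frame(v = 0))), "female")
})

test_that("stepwise selection isolates informative variables", {
  # one separated variable among pure noise: selected alone in most seeds
  hits <- vapply(1:60, function(seed) {
    set.seed(seed)
    n <- 15L
    d <- data.frame(sex = rep(c("male", "female"), each = n),
                    sig = c(rnorm(n, 3), rnorm(n, 0)),
                    n1 = rnorm(2 * n), n2 = rnorm(2 * n),
                    n3 = rnorm(2 * n), n4 = rnorm(2 * n))
    sel <- stepwise_select(d, c("sig", paste0("n", 1:4)))$selected
    "sig" %in% sel
  }, logical(1))
  expect_equal(mean(hits), 1)
  # duplicated informative variable: exactly one of the pair enters
  set.seed(7)
  n <- 20L
  d2 <- data.frame(sex = rep(c("male", "female"), each = n),
                   a = c(rnorm(n, 2), rnorm(n, 0)))
  d2$b <- d2$a
  sel2 <- stepwise_select(d2, c("a", "b"))$selected
  expect_equal(length(sel2), 1L)
  # all-noise candidates: empty model in most seeds (partial-F gate size)
  empties <- vapply(1:100, function(seed) {
    set.seed(seed + 1000)
    d3 <- data.frame(sex = rep(c("male", "female"), each = 15),
                     v1 = rnorm(30), v2 = rnorm(30), v3 = rnorm(30))
    length(stepwise_select(d3, c("v1", "v2", "v3"))$selected) == 0L
  }, logical(1))
  expect_gt(mean(empties), 0.75)
  # empty selection is a valid sdfa result
  set.seed(1001)
  d4 <- data.frame(sex = rep(c("male", "female"), each = 15), v1 = rnorm(30))
  fit4 <- sdfa(sex ~ v1, d4)
  if (length(fit4$variables) == 0L)
    expect_error(predict(fit4, d4), class = "osteo_format_error")
})

test_that("stepwise path matches the subset-enumeration oracle", {
  for (seed in 1:60) {
    d <- random_small_cohort(seed)
    cands <- setdiff(names(d), "sex")
    got <- stepwise_select(d, cands)$selected
    want <- oracle_stepwise(d, cands)
    expect_identical(got, want,
                     label = sprintf("seed %d: [%s] vs oracle [%s]", seed,
                                     paste(got, collapse = ","),
                                     paste(want, collapse = ",")))
  }
})

test_that("published registry is coherent and scores the reference means", {
  reg <- published_functions()
  expect_length(reg, 10L)
  f4 <- published_function("left", 4)
  expect_equal(unname(coef(f4)), c(50.593, -20.593))
  f5r <- published_function("right", 5)
  expect_equal(unname(f5r$coefficients), c(55.060, -9.850))
  expect_equal(f5r$constant, -4.021)
  # sectioning points sit at the centroid midpoints as printed
  for (m in reg)
    expect_lt(abs(m$sectioning_point - mean(m$centroids)), 1e-3 + 1e-9)
  # Bartlett chi-square is consistent with the printed lambda at n = 59
  f1 <- published_function("left", 1)
  chi <- -(59 - 1 - (3 + 2) / 2) * log(f1$wilks_lambda)
  expect_equal(chi, f1$chi_square, tolerance = 0.002)
  # standardized coefficient = unstandardized x pooled SD (left function 4)
  st <- mt_reference_stats("left", 4, "sa_v")
  pooled_sd <- sqrt(mean(st$sd^2))
  expect_equal(f4$coefficients[["sa_v"]] * pooled_sd, 1.000, tolerance = 0.01)
  # scoring reference group means recovers the printed centroids
  m1 <- mt_reference_stats("left", 1)
  means_m <- setNames(m1$mean[m1$sex == "male"], m1$variable[m1$sex == "male"])
  y <- predict(f1, as.list(means_m), type = "score")
  expect_equal(y, f1$centroids[["male"]], tolerance = 0.05)
  # classification follows the sign convention of the male centroid
  f3 <- published_function("left", 3)
  expect_identical(unname(predict(f3, data.frame(sa_v = 0.386, Hn = 0.198))),
                   "male")
  expect_identical(unname(predict(f3, data.frame(sa_v = 0.450, Hn = 0.192))),
                   "female")
  # missing variable errors by name
  expect_error(predict(f3, data.frame(sa_v = 0.4)), "Hn",
               class = "osteo_format_error")
})

test_that("leave-one-out reporting matches construction cases", {
  # perfectly separated groups: 100 percent in both blocks
  d <- data.frame(sex = rep(c("male", "female"), each = 10),
                  v = c(seq(10, 11, length.out = 10),
                        seq(0, 1, length.out = 10)))
  rep0 <- loo_accuracy(d, variables = "v")
  expect_equal(rep0$original$total_percent, 100)
  expect_equal(rep0$cross_validated$total_percent, 100)
  expect_equal(unname(rep0$original$per_group[, "percent"]), c(100, 100))
  # single record per group is not enough
  expect_error(loo_accuracy(d[c(1, 11), ], variables = "v"),
               class = "osteo_format_error")
  # report counts are consistent with percentages
  d2 <- sim_lr_cohort(3)
  rep2 <- loo_accuracy(d2, variables = c("sa_v", "Hn"))
  for (blk in list(rep2$original, rep2$cross_validated)) {
    pg <- blk$per_group
    expect_equal(pg[, "percent"], 100 * pg[, "correct"] / pg[, "total"],
                 ignore_attr = TRUE)
    expect_gte(min(pg[, "percent"]), 0)
  }
  # cross-validated accuracy never exceeds what separable data allow
  expect_lte(rep2$cross_validated$total_percent, 100)
})

test_that("sectioning points follow the midpoint and prior-shift rules", {
  expect_equal(sectioning_point(1.554, -1.503), 0.0255, tolerance = 1e-12)
  expect_equal(sectioning_point(1.536, -1.589), -0.0265, tolerance = 1e-12)
  expect_equal(sectioning_point(1.7, -1.7), 0)
  expect_error(sectioning_point(1, 1), class = "osteo_degenerate_error")
  # a higher prior for group b moves the cut toward group a
  expect_gt(sectioning_point(1, -1, priors = c(0.2, 0.8)), 0)
})
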