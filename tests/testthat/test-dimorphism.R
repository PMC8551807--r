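test_that("dimorphism index reproduces reference values and its symmetries", {
  expect_equal(sdi(0.256, 0.289), -6.055, tolerance = 5e-4)
  expect_equal(sdi(0.087, 0.078), 5.455, tolerance = 5e-4)
  expect_equal(sdi(1.5, 1.5), 0)
  set.seed(21)
  for (i in 1:50) {
    a <- runif(1, 0.01, 10); b <- runif(1, 0.01, 10); k <- runif(1, 0.1, 100)
    expect_identical(sdi(a, b), -sdi(b, a))
    expect_equal(sdi(k * a, k * b), sdi(a, b), tolerance = 1e-12)
  }
  expect_error(sdi(0, 0), class = "osteo_format_error")
})

test_that("test dispatch follows normality and homoscedasticity", {
  # heavy-tailed contamination in one group -> Mann-Whitney
  set.seed(5)
  d <- data.frame(sex = rep(c("male", "female"), each = 30),
                  v = c(rnorm(29), 25, rnorm(30)))
  cmp <- compare_sexes(d, "v")
  expect_equal(cmp$test_used, "mann_whitney")
  expect_true(min(cmp$shapiro_p) < 0.05)
  # strongly heteroscedastic normal groups -> Welch
  found_welch <- FALSE
  for (seed in 1:20) {
    set.seed(seed)
    d2 <- data.frame(sex = rep(c("male", "female"), each = 40),
                     v = c(rnorm(40, 0, 1), rnorm(40, 0, 5)))
    cmp2 <- compare_sexes(d2, "v")
    if (cmp2$test_used == "welch") found_welch <- TRUE
    # never a pooled t when Levene rejects
    if (cmp2$levene_p < 0.05) expect_true(cmp2$test_used != "t")
  }
  expect_true(found_welch)
  # 3-pooled-SD separation is always detected
  set.seed(8)
  d3 <- data.frame(sex = rep(c("male", "female"), each = 30),
                   v = c(rnorm(30, 3), rnorm(30, 0)))
  expect_lt(compare_sexes(d3, "v")$p_value, 0.01)
  expect_error(compare_sexes(d3[c(1:2, 31:60), ], "v"),
               class = "osteo_format_error")
})

test_that("dispatched p-values keep the nominal type-I rate under the null", {
  set.seed(99)
  hits <- 0L
  n_rep <- 400L
  for (i in seq_len(n_rep)) {
    d <- data.frame(sex = rep(c("male", "female"), each = 30), v = rnorm(60))
    cmp <- compare_sexes(d, "v")
    expect_true(cmp$test_used %in% c("t", "welch", "mann_whitney"))
    hits <- hits + (cmp$p_value < 0.05)
  }
  expect_gt(hits / n_rep, 0.02)
  expect_lt(hits / n_rep, 0.09)
})

test_that("correlation screening flags duplicates and built-in associations", {
  set.seed(31)
  d <- simulate_cohort(cohort_spec("left", 3), seed = 31)
  d$dup <- d$sa_v
  scr <- correlation_screen(d, c(bone_variables(), "dup"))
  expect_true(any(scr$flagged$var1 == "sa_v" & scr$flagged$var2 == "dup" |
                  scr$flagged$var1 == "dup" & scr$flagged$var2 == "sa_v"))
  # triplet members are structurally collinear only via renormalization;
  # independent simulated variables must not produce spurious flags
  indep <- data.frame(sex = rep(c("male", "female"), each = 30),
                      matrix(rnorm(60 * 5), 60, 5,
                             dimnames = list(NULL, paste0("v", 1:5))))
  n_flag <- sum(vapply(1:25, function(s) {
    set.seed(s)
    indep[-1] <- matrix(rnorm(60 * 5), 60, 5)
    nrow(correlation_screen(indep, paste0("v", 1:5))$flagged)
  }, numeric(1)))
  expect_lte(n_flag, 1)
  # constant variable is excluded, not fatal
  d$flat <- 1
  scr2 <- correlation_screen(d, c("sa_v", "Hn", "flat"))
  expect_equal(scr2$constant, "flat")
  expect_false("flat" %in% colnames(scr2$pearson))
})

test_that("height-linked SA:V produces the expected Spearman range", {
  set.seed(17)
  rs <- vapply(1:20, function(s) {
    d <- simulate_cohort(cohort_spec("left", 3), seed = s, covariates = TRUE,
                         sa_v_height_r = -0.7)
    scr <- correlation_screen(d)
    scr$spearman["sa_v", "height_cm"]
  }, numeric(1))
  expect_lt(mean(rs), -0.5)
  expect_gt(mean(rs), -0.85)
})

test_that("assumption battery flags planted outliers and passes clean nulls", {
  set.seed(41)
  d <- simulate_cohort(cohort_spec("left", 3), seed = 41)
  vars <- c("sa_v", "Hn", "density")
  bat <- assumption_battery(d, vars)
  expect_equal(sum(bat$mahalanobis$outlier), 0)
  expect_true(bat$box_m_pass)
  # displace one record 10 SDs along one variable
  d2 <- d
  d2$sa_v[5] <- d2$sa_v[5] + 10 * sd(d2$sa_v[d2$sex == "male"])
  bat2 <- assumption_battery(d2, vars, outlier_alpha = 0.001)
  expect_true(bat2$mahalanobis$outlier[bat2$mahalanobis$row == 5])
  expect_error(assumption_battery(d[1:4, ], vars), class = "osteo_format_error")
  # collinear variables produce a singular-covariance error naming them
  d3 <- d; d3$dup <- d3$sa_v
  expect_error(assumption_battery(d3, c("sa_v", "dup")),
               class = "osteo_singular_error")
})

test_that("Box's M holds its size under equal-covariance nulls", {
  set.seed(55)
  passes <- vapply(1:200, function(i) {
    X <- matrix(rnorm(60 * 3), 60, 3)
    g <- rep(c("a", "b"), each = 30)
    osteoinertia:::box_m_test(X, g)$p > 0.001
  }, logical(1))
  expect_gte(mean(passes), 0.98)
})

test_that("Mardia p-values are uniform under multivariate normality", {
  set.seed(66)
  ps <- t(vapply(1:200, function(i) {
    m <- osteoinertia:::mardia_test(matrix(rnorm(200 * 3), 200, 3))
    c(m$skew_p, m$kurt_p)
  }, numeric(2)))
  expect_gt(stats::ks.test(ps[, 1], "punif")$p.value, 0.01)
  expect_gt(stats::ks.test(ps[, 2], "punif")$p.value, 0.01)
})

test_that("ICC(A,1) matches its variance-component constructions", {
  x <- c(3.1, 4.2, 5.3, 6.4, 7.5)
  expect_equal(icc_agreement(x, x)$icc, 1.0)
  # between-subject SD 10x error SD -> ICC about 0.99
  set.seed(77)
  subj <- rnorm(60, sd = 10)
  icc_hi <- icc_agreement(subj + rnorm(60), subj + rnorm(60))$icc
  expect_gt(icc_hi, 0.97)
  # independent noise -> ICC centered on zero (null sd is about 0.13 at
  # n = 60, so individual draws up to ~0.3 are expected)
  iccs <- vapply(1:40, function(s) {
    set.seed(s)
    icc_agreement(rnorm(60), rnorm(60))$icc
  }, numeric(1))
  expect_lt(abs(mean(iccs)), 0.05)
  expect_lt(quantile(abs(iccs), 0.95), 0.3)
  expect_error(icc_agreement(rep(1, 10), rep(1, 10)),
               class = "osteo_degenerate_error")
  expect_error(icc_agreement(1:2, 1:2), class = "osteo_format_error")
})
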