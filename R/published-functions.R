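## Registry of the ten published metatarsal sex-estimation discriminant
## functions (five per side) and the per-sex descriptive statistics of the
## 30-male / 30-female reference cohort they were derived from. Coefficients,
## constants, centroids and sectioning points are stored exactly as printed;
## the variable names map onto the cohort schema as sa_v (surface-area-to-
## volume ratio), density (bone density), Hn (normalized height) and pmi_z
## (normalized principal moment about the long axis).

published_model <- function(side, metatarsal, variables, coefficients,
                            constant, std, structure_mat, lambda, chi_square,
                            centroid_male, centroid_female, sectioning) {
  structure(list(variables = variables,
                 coefficients = setNames(coefficients, variables),
                 constant = constant,
                 std_coefficients = setNames(std, variables),
                 structure_matrix = setNames(structure_mat, variables),
                 centroids = c(male = centroid_male, female = centroid_female),
                 sectioning_point = sectioning,
                 wilks_lambda = lambda, chi_square = chi_square,
                 chi_df = length(variables),
                 p_value = pchisq(chi_square, length(variables),
                                  lower.tail = FALSE),
                 group = "sex", levels = c("male", "female"),
                 fitted = FALSE, side = side, metatarsal = metatarsal),
            class = "sdfa")
}

#' Published metatarsal sex-estimation functions
#'
#' Returns the registry of the ten published two-group discriminant
#' functions (left and right, first to fifth metatarsal), as `sdfa` objects
#' usable with [predict.sdfa()]. All numbers are stored as printed;
#' `published_function()` retrieves a single entry.
#'
#' @return A named list of 10 `sdfa` objects, keys `left_1` ... `right_5`.
#' @examples
#' f <- published_function("left", 4)
#' coef(f)
#' predict(f, data.frame(sa_v = 0.377), type = "score")
#' @export
published_functions <- function() {
  list(
    left_1 = published_model("left", 1L,
      c("sa_v", "density", "Hn"), c(-72.779, 13.129, 64.683), -13.556,
      std = c(-1.098, 0.745, 0.504), structure_mat = c(-0.686, 0.144, 0.278),
      lambda = 0.283, chi_square = 69.969,
      centroid_male = 1.536, centroid_female = -1.589, sectioning = -0.027),
    left_2 = published_model("left", 2L,
      c("sa_v", "Hn"), c(39.926, -35.974), -8.664,
      std = c(0.974, -0.325), structure_mat = c(0.946, -0.242),
      lambda = 0.380, chi_square = 55.225,
      centroid_male = -1.257, centroid_female = 1.257, sectioning = 0.000),
    left_3 = published_model("left", 3L,
      c("sa_v", "Hn"), c(51.104, -38.990), -13.755,
      std = c(0.984, -0.324), structure_mat = c(0.947, -0.210),
      lambda = 0.241, chi_square = 81.189,
      centroid_male = -1.746, centroid_female = 1.746, sectioning = 0.000),
    left_4 = published_model("left", 4L,
      "sa_v", 50.593, -20.593,
      std = 1.000, structure_mat = 1.000,
      lambda = 0.301, chi_square = 69.087,
      centroid_male = -1.499, centroid_female = 1.499, sectioning = 0.000),
    left_5 = published_model("left", 5L,
      c("sa_v", "density"), c(51.174, -4.971), -10.718,
      std = c(1.024, -0.327), structure_mat = c(0.948, -0.090),
      lambda = 0.345, chi_square = 60.676,
      centroid_male = -1.355, centroid_female = 1.355, sectioning = 0.000),
    right_1 = published_model("right", 1L,
      c("sa_v", "pmi_z", "density"), c(-61.716, 77.849, 8.292), -2.848,
      std = c(-0.911, 0.535, 0.530), structure_mat = c(-0.728, 0.504, 0.127),
      lambda = 0.293, chi_square = 68.207,
      centroid_male = 1.554, centroid_female = -1.503, sectioning = 0.026),
    right_2 = published_model("right", 2L,
      c("sa_v", "pmi_z"), c(37.552, -124.899), -10.559,
      std = c(0.888, -0.410), structure_mat = c(0.912, -0.463),
      lambda = 0.317, chi_square = 65.407,
      centroid_male = -1.442, centroid_female = 1.442, sectioning = 0.000),
    right_3 = published_model("right", 3L,
      c("sa_v", "Hn"), c(52.538, -35.799), -14.859,
      std = c(0.995, -0.333), structure_mat = c(0.944, -0.180),
      lambda = 0.224, chi_square = 85.167,
      centroid_male = -1.828, centroid_female = 1.828, sectioning = 0.000),
    right_4 = published_model("right", 4L,
      c("sa_v", "density", "Hn"), c(54.196, -8.403, -37.812), -1.557,
      std = c(1.087, -0.528, -0.333), structure_mat = c(0.822, -0.058, -0.227),
      lambda = 0.213, chi_square = 87.386,
      centroid_male = -1.890, centroid_female = 1.890, sectioning = 0.000),
    right_5 = published_model("right", 5L,
      c("sa_v", "density"), c(55.060, -9.850), -4.021,
      std = c(1.092, -0.610), structure_mat = c(0.833, -0.147),
      lambda = 0.277, chi_square = 73.259,
      centroid_male = -1.590, centroid_female = 1.590, sectioning = 0.000)
  )
}

#' @rdname published_functions
#' @param side `"left"` or `"right"`.
#' @param metatarsal metatarsal index 1 to 5.
#' @export
published_function <- function(side = c("left", "right"), metatarsal) {
  side <- match.arg(side)
  metatarsal <- as.integer(metatarsal)
  if (!metatarsal %in% 1:5)
    stop_osteo("metatarsal must be 1..5", "osteo_format_error")
  published_functions()[[paste(side, metatarsal, sep = "_")]]
}

## side, metatarsal, variable -> (mean, sd, min, max) per sex. One call per
## printed table row; male block first, then female.
.ref_rows <- function() {
  rw <- function(side, mt, var, m_mean, m_sd, m_min, m_max,
                 f_mean, f_sd, f_min, f_max) {
    data.frame(side = side, metatarsal = mt, variable = var,
               sex = c("male", "female"),
               mean = c(m_mean, f_mean), sd = c(m_sd, f_sd),
               min = c(m_min, f_min), max = c(m_max, f_max))
  }
  rbind(
    ## normalized linear variables
    rw("left", 1L, "Ln", 0.553, 0.014, 0.528, 0.577, 0.563, 0.011, 0.543, 0.586),
    rw("right", 1L, "Ln", 0.550, 0.013, 0.525, 0.574, 0.563, 0.011, 0.542, 0.583),
    rw("left", 1L, "Wn", 0.251, 0.008, 0.225, 0.265, 0.247, 0.006, 0.238, 0.265),
    rw("right", 1L, "Wn", 0.253, 0.008, 0.224, 0.269, 0.246, 0.005, 0.233, 0.255),
    rw("left", 1L, "Hn", 0.196, 0.008, 0.182, 0.214, 0.190, 0.009, 0.174, 0.210),
    rw("right", 1L, "Hn", 0.197, 0.008, 0.182, 0.215, 0.191, 0.008, 0.174, 0.202),
    rw("left", 2L, "Ln", 0.659, 0.015, 0.629, 0.687, 0.666, 0.010, 0.639, 0.686),
    rw("right", 2L, "Ln", 0.658, 0.015, 0.624, 0.693, 0.665, 0.011, 0.637, 0.681),
    rw("left", 2L, "Wn", 0.145, 0.008, 0.133, 0.164, 0.143, 0.006, 0.132, 0.157),
    rw("right", 2L, "Wn", 0.145, 0.008, 0.129, 0.162, 0.142, 0.007, 0.122, 0.157),
    rw("left", 2L, "Hn", 0.196, 0.010, 0.178, 0.220, 0.191, 0.008, 0.178, 0.218),
    rw("right", 2L, "Hn", 0.197, 0.010, 0.173, 0.219, 0.193, 0.008, 0.176, 0.207),
    rw("left", 3L, "Ln", 0.663, 0.013, 0.636, 0.687, 0.672, 0.010, 0.650, 0.690),
    rw("right", 3L, "Ln", 0.663, 0.014, 0.634, 0.684, 0.673, 0.012, 0.647, 0.692),
    rw("left", 3L, "Wn", 0.139, 0.008, 0.125, 0.156, 0.136, 0.006, 0.123, 0.152),
    rw("right", 3L, "Wn", 0.139, 0.008, 0.128, 0.156, 0.136, 0.007, 0.121, 0.152),
    rw("left", 3L, "Hn", 0.198, 0.009, 0.178, 0.222, 0.192, 0.008, 0.173, 0.206),
    rw("right", 3L, "Hn", 0.198, 0.009, 0.180, 0.221, 0.192, 0.009, 0.172, 0.213),
    rw("left", 4L, "Ln", 0.670, 0.012, 0.645, 0.696, 0.680, 0.010, 0.659, 0.699),
    rw("right", 4L, "Ln", 0.668, 0.013, 0.638, 0.697, 0.680, 0.011, 0.656, 0.697),
    rw("left", 4L, "Wn", 0.148, 0.007, 0.135, 0.166, 0.146, 0.008, 0.135, 0.168),
    rw("right", 4L, "Wn", 0.149, 0.006, 0.138, 0.159, 0.145, 0.007, 0.127, 0.160),
    rw("left", 4L, "Hn", 0.182, 0.010, 0.160, 0.209, 0.174, 0.008, 0.161, 0.189),
    rw("right", 4L, "Hn", 0.183, 0.010, 0.163, 0.213, 0.175, 0.007, 0.161, 0.192),
    rw("left", 5L, "Ln", 0.658, 0.014, 0.630, 0.706, 0.667, 0.012, 0.642, 0.692),
    rw("right", 5L, "Ln", 0.661, 0.013, 0.637, 0.701, 0.668, 0.010, 0.642, 0.693),
    rw("left", 5L, "Wn", 0.192, 0.010, 0.163, 0.207, 0.190, 0.008, 0.173, 0.205),
    rw("right", 5L, "Wn", 0.191, 0.011, 0.164, 0.206, 0.189, 0.007, 0.175, 0.203),
    rw("left", 5L, "Hn", 0.150, 0.008, 0.131, 0.173, 0.143, 0.007, 0.130, 0.158),
    rw("right", 5L, "Hn", 0.148, 0.008, 0.134, 0.168, 0.143, 0.007, 0.130, 0.155),
    ## surface-area-to-volume ratio and bone density
    rw("left", 1L, "sa_v", 0.256, 0.016, 0.224, 0.297, 0.289, 0.014, 0.262, 0.315),
    rw("right", 1L, "sa_v", 0.256, 0.016, 0.223, 0.299, 0.290, 0.013, 0.263, 0.315),
    rw("left", 1L, "density", 1.602, 0.059, 1.452, 1.718, 1.577, 0.054, 1.436, 1.670),
    rw("right", 1L, "density", 1.605, 0.072, 1.462, 1.744, 1.583, 0.056, 1.443, 1.681),
    rw("left", 2L, "sa_v", 0.362, 0.022, 0.328, 0.420, 0.420, 0.026, 0.359, 0.470),
    rw("right", 2L, "sa_v", 0.359, 0.020, 0.332, 0.413, 0.421, 0.027, 0.366, 0.487),
    rw("left", 2L, "density", 1.710, 0.078, 1.522, 1.907, 1.748, 0.077, 1.592, 1.909),
    rw("right", 2L, "density", 1.710, 0.085, 1.522, 1.913, 1.730, 0.069, 1.586, 1.860),
    rw("left", 3L, "sa_v", 0.386, 0.018, 0.348, 0.417, 0.450, 0.021, 0.407, 0.502),
    rw("right", 3L, "sa_v", 0.383, 0.016, 0.346, 0.407, 0.448, 0.022, 0.409, 0.504),
    rw("left", 3L, "density", 1.661, 0.077, 1.502, 1.844, 1.666, 0.068, 1.514, 1.777),
    rw("right", 3L, "density", 1.660, 0.075, 1.496, 1.803, 1.652, 0.064, 1.516, 1.775),
    rw("left", 4L, "sa_v", 0.377, 0.016, 0.341, 0.418, 0.437, 0.023, 0.392, 0.487),
    rw("right", 4L, "sa_v", 0.375, 0.016, 0.335, 0.408, 0.437, 0.023, 0.392, 0.484),
    rw("left", 4L, "density", 1.631, 0.077, 1.429, 1.760, 1.624, 0.061, 1.458, 1.751),
    rw("right", 4L, "density", 1.633, 0.071, 1.429, 1.731, 1.620, 0.053, 1.482, 1.718),
    rw("left", 5L, "sa_v", 0.346, 0.017, 0.313, 0.388, 0.398, 0.023, 0.354, 0.444),
    rw("right", 5L, "sa_v", 0.345, 0.016, 0.307, 0.370, 0.398, 0.023, 0.358, 0.450),
    rw("left", 5L, "density", 1.682, 0.077, 1.466, 1.798, 1.666, 0.053, 1.569, 1.813),
    rw("right", 5L, "density", 1.682, 0.070, 1.466, 1.788, 1.653, 0.053, 1.549, 1.800),
    ## normalized principal moments of inertia
    rw("left", 1L, "pmi_x", 0.462, 0.005, 0.446, 0.470, 0.466, 0.003, 0.460, 0.471),
    rw("right", 1L, "pmi_x", 0.461, 0.006, 0.447, 0.470, 0.465, 0.003, 0.460, 0.471),
    rw("left", 1L, "pmi_y", 0.452, 0.005, 0.444, 0.467, 0.457, 0.004, 0.449, 0.467),
    rw("right", 1L, "pmi_y", 0.451, 0.005, 0.443, 0.463, 0.456, 0.003, 0.450, 0.466),
    rw("left", 1L, "pmi_z", 0.087, 0.009, 0.064, 0.099, 0.078, 0.006, 0.063, 0.089),
    rw("right", 1L, "pmi_z", 0.088, 0.009, 0.067, 0.103, 0.078, 0.005, 0.068, 0.089),
    rw("left", 2L, "pmi_x", 0.478, 0.003, 0.472, 0.485, 0.480, 0.002, 0.476, 0.483),
    rw("right", 2L, "pmi_x", 0.478, 0.003, 0.472, 0.485, 0.480, 0.002, 0.477, 0.482),
    rw("left", 2L, "pmi_y", 0.488, 0.002, 0.484, 0.491, 0.489, 0.001, 0.486, 0.491),
    rw("right", 2L, "pmi_y", 0.487, 0.003, 0.474, 0.490, 0.489, 0.001, 0.486, 0.492),
    rw("left", 2L, "pmi_z", 0.034, 0.004, 0.024, 0.042, 0.031, 0.003, 0.026, 0.038),
    rw("right", 2L, "pmi_z", 0.035, 0.001, 0.026, 0.044, 0.031, 0.002, 0.026, 0.037),
    rw("left", 3L, "pmi_x", 0.477, 0.003, 0.470, 0.484, 0.479, 0.002, 0.476, 0.483),
    rw("right", 3L, "pmi_x", 0.477, 0.003, 0.469, 0.483, 0.480, 0.002, 0.476, 0.483),
    rw("left", 3L, "pmi_y", 0.489, 0.002, 0.486, 0.492, 0.490, 0.001, 0.488, 0.492),
    rw("right", 3L, "pmi_y", 0.488, 0.002, 0.485, 0.492, 0.490, 0.001, 0.487, 0.492),
    rw("left", 3L, "pmi_z", 0.034, 0.004, 0.024, 0.044, 0.031, 0.003, 0.027, 0.035),
    rw("right", 3L, "pmi_z", 0.035, 0.004, 0.025, 0.046, 0.030, 0.003, 0.027, 0.036),
    rw("left", 4L, "pmi_x", 0.479, 0.003, 0.473, 0.486, 0.481, 0.002, 0.477, 0.484),
    rw("right", 4L, "pmi_x", 0.478, 0.003, 0.472, 0.484, 0.481, 0.002, 0.477, 0.486),
    rw("left", 4L, "pmi_y", 0.487, 0.002, 0.484, 0.492, 0.488, 0.001, 0.485, 0.490),
    rw("right", 4L, "pmi_y", 0.487, 0.002, 0.483, 0.491, 0.488, 0.002, 0.482, 0.491),
    rw("left", 4L, "pmi_z", 0.034, 0.004, 0.023, 0.041, 0.031, 0.003, 0.026, 0.037),
    rw("right", 4L, "pmi_z", 0.034, 0.004, 0.026, 0.041, 0.031, 0.003, 0.026, 0.036),
    rw("left", 5L, "pmi_x", 0.484, 0.003, 0.479, 0.491, 0.485, 0.002, 0.481, 0.487),
    rw("right", 5L, "pmi_x", 0.484, 0.002, 0.480, 0.489, 0.485, 0.002, 0.482, 0.488),
    rw("left", 5L, "pmi_y", 0.475, 0.004, 0.468, 0.487, 0.477, 0.003, 0.470, 0.482),
    rw("right", 5L, "pmi_y", 0.476, 0.004, 0.468, 0.484, 0.477, 0.003, 0.472, 0.482),
    rw("left", 5L, "pmi_z", 0.041, 0.006, 0.022, 0.051, 0.038, 0.004, 0.032, 0.049),
    rw("right", 5L, "pmi_z", 0.040, 0.006, 0.027, 0.052, 0.038, 0.004, 0.031, 0.046)
  )
}

#' Reference cohort statistics for the published functions
#'
#' Per-sex mean, SD, min and max of the eight bone variables in the
#' 30-male / 30-female reference cohort behind the published discriminant
#' functions, for each side and metatarsal. These are the default
#' parameters of [cohort_spec()].
#'
#' @param side optional `"left"`/`"right"` filter.
#' @param metatarsal optional metatarsal index filter (1..5).
#' @param variable optional variable name filter.
#' @return Data frame with columns `side, metatarsal, variable, sex, mean,
#'   sd, min, max`.
#' @examples
#' mt_reference_stats("left", 3, "sa_v")
#' @export
mt_reference_stats <- function(side = NULL, metatarsal = NULL, variable = NULL) {
  d <- .ref_rows()
  if (!is.null(side)) d <- d[d$side == side, , drop = FALSE]
  if (!is.null(metatarsal)) d <- d[d$metatarsal == as.integer(metatarsal), ,
                                   drop = FALSE]
  if (!is.null(variable)) d <- d[d$variable %in% variable, , drop = FALSE]
  row.names(d) <- NULL
  d
}
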