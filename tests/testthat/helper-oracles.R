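# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: Wilks' lambda comes from stats::manova / aov,
# the icosphere is an analytic triangulation, and the stepwise replay reads
# lambdas from a pre-enumerated subset table.

# Wilks' lambda via R's MANOVA machinery (aov for a single response).
oracle_wilks <- function(data, vars, group = "sex") {
  if (length(vars) == 0L) return(1)
  g <- factor(data[[group]])
  if (length(vars) == 1L) {
    ss <- summary(aov(data[[vars]] ~ g))[[1]][["Sum Sq"]]
    return(ss[2] / sum(ss))
  }
  Y <- as.matrix(data[vars])
  fit <- manova(Y ~ g)
  summary(fit, test = "Wilks")$stats[1, "Wilks"]
}

# Brute-force stepwise: enumerate lambda for every candidate subset up
# front, then replay the entry/removal rules from that table alone.
oracle_stepwise <- function(data, candidates, group = "sex",
                            f_enter = 3.84, f_remove = 2.71) {
  n <- nrow(data)
  subsets <- unlist(lapply(0:length(candidates), function(k)
    combn(candidates, k, simplify = FALSE)), recursive = FALSE)
  keyof <- function(v) if (length(v) == 0L) "(none)" else
    paste(sort(v), collapse = "+")
  lam <- setNames(
    vapply(subsets, function(s) oracle_wilks(data, s, group), numeric(1)),
    vapply(subsets, keyof, character(1)))
  pf_gate <- function(l_small, l_large, p) (l_small / l_large - 1) * (n - 2 - p)
  current <- character(0)
  repeat {
    changed <- FALSE
    pool <- setdiff(candidates, current)
    if (length(pool)) {
      lnew <- vapply(pool, function(v) lam[[keyof(c(current, v))]], numeric(1))
      best <- which.min(lnew)
      Fe <- pf_gate(lam[[keyof(current)]], lnew[best], length(current))
      if (is.finite(Fe) && Fe >= f_enter) {
        current <- c(current, pool[best])
        changed <- TRUE
      }
    }
    repeat {
      if (length(current) == 0L) break
      Fr <- vapply(current, function(v)
        pf_gate(lam[[keyof(setdiff(current, v))]], lam[[keyof(current)]],
                length(current) - 1L), numeric(1))
      worst <- which.min(Fr)
      if (Fr[worst] < f_remove) {
        current <- setdiff(current, current[worst])
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  current
}

# Random two-group cohorts for the stepwise oracle sweep: a mix of pure
# noise and separated variables, occasionally collinear.
random_small_cohort <- function(seed) {
  set.seed(seed)
  n_each <- sample(5:10, 1)
  p <- sample(1:3, 1)
  sep <- runif(p, 0, 3) * rbinom(p, 1, 0.5)
  g <- rep(c("male", "female"), each = n_each)
  X <- sapply(seq_len(p), function(j)
    rnorm(2 * n_each) + sep[j] * (g == "male"))
  X <- matrix(X, ncol = p)
  colnames(X) <- paste0("v", seq_len(p))
  data.frame(sex = g, X, stringsAsFactors = FALSE)
}

# Icosphere: subdivided icosahedron projected onto the sphere.
make_icosphere <- function(radius = 1, subdivisions = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nf <- nrow(f)
    newv <- list(v)
    mid_cache <- new.env()
    vcount <- nrow(v)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- mid_cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      vcount <<- vcount + 1L
      newv[[length(newv) + 1L]] <<- matrix(m, 1)
      mid_cache[[key]] <- vcount
      vcount
    }
    fnew <- matrix(0L, 4L * nf, 3L)
    for (i in seq_len(nf)) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      fnew[4 * i - 3, ] <- c(a, ab, ca)
      fnew[4 * i - 2, ] <- c(b, bc, ab)
      fnew[4 * i - 1, ] <- c(cc, ca, bc)
      fnew[4 * i, ] <- c(ab, bc, ca)
    }
    v <- do.call(rbind, newv)
    f <- fnew
  }
  structure(list(vertices = v * radius, faces = f, watertight = TRUE),
            class = "surface_mesh")
}

# Explicit unit-cube mesh (12 triangles, outward orientation).
unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  colnames(v) <- NULL
  quad <- function(a, b, cc, d) rbind(c(a, b, cc), c(a, cc, d))
  f <- rbind(quad(1, 3, 4, 2),   # z = 0, normal -z
             quad(5, 6, 8, 7),   # z = 1, normal +z
             quad(1, 2, 6, 5),   # y = 0
             quad(3, 7, 8, 4),   # y = 1
             quad(1, 5, 7, 3),   # x = 0
             quad(2, 4, 8, 6))   # x = 1
  structure(list(vertices = v, faces = f, watertight = TRUE),
            class = "surface_mesh")
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol * abs(expected)),
              label = sprintf("max rel err %.3g vs tol %.3g",
                              max(abs(actual - expected) / abs(expected)), tol))
}

quaternion_rotation_for_test <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
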