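test_that("saturation stoichiometry follows the lattice closed form", {
  expect_equal(saturation_stoichiometry(2, 13), 420 / 247)
  expect_equal(saturation_stoichiometry(1, 13), 120 / 91)
  expect_equal(saturation_stoichiometry(0, 13), 0)
  # monotone in ring count, approaching the interior limit 3/13 per actin
  s <- sapply(1:30, saturation_stoichiometry, units_per_repeat = 13)
  expect_true(all(diff(s) > 0))
  expect_lt(max(s), 10 * 3 / 13)
  expect_lt(10 * 3 / 13 - s[30], 0.06)   # slow O(1/r) boundary convergence
  expect_error(saturation_stoichiometry(-1), "non-negative")
})

test_that("packing density conventions are reported and bracket the model", {
  d <- packing_density()
  expect_named(d$matthews, c("per_filament_cell", "hull", "hull_margin"))
  expect_equal(unname(d$matthews), unname(d$volumes) / d$mass)
  expect_true(all(d$matthews > 0))
  expect_lt(d$matthews[["hull"]], d$matthews[["hull_margin"]])
  expect_lt(d$matthews[["hull_margin"]], d$matthews[["per_filament_cell"]])

  # bare actin with unit masses: per-filament cell is an exact closed form
  bare <- packing_density(crosslinkers_per_edge = c(),
                          masses = c(actin = 1, fimbrin = 1, villin = 1))
  expect_equal(bare$matthews[["per_filament_cell"]],
               (sqrt(3) / 2 * 120^2 * 13 * 27.57) / 13)
  expect_error(packing_density(masses = c(actin = 0, fimbrin = 1,
                                          villin = 1)), "positive")
})

test_that("hexagon hull volume agrees with Monte-Carlo rejection sampling", {
  R <- 240; h <- 13 * 27.57
  analytic <- 3 * sqrt(3) / 2 * R^2 * h
  set.seed(11)
  n <- 2e5
  px <- runif(n, -R, R); py <- runif(n, -R * sqrt(3) / 2, R * sqrt(3) / 2)
  # hexagon with flat sides at y = +-R sqrt(3)/2 and vertices at +-R
  inside <- abs(py) <= R * sqrt(3) / 2 &
    abs(py) <= sqrt(3) * (R - abs(px)) + 1e-12
  mc <- mean(inside) * (2 * R) * (R * sqrt(3)) * h
  expect_equal(mc, analytic, tolerance = 0.01)
  expect_equal(packing_density(masses = c(actin = 1, fimbrin = 1,
                                          villin = 1),
                               crosslinkers_per_edge = c())$volumes[["hull"]],
               analytic)
})

test_that("spectrin length from membrane density matches a constructed net", {
  expect_equal(spectrin_length_from_density(1e5, 135), 68.385,
               tolerance = 1e-3)
  # a ~ n^(-1/2)
  expect_equal(spectrin_length_from_density(4e5, 135),
               spectrin_length_from_density(1e5, 135) / 2)
  expect_error(spectrin_length_from_density(0, 135), "positive")

  # explicit construction oracle: a periodic triangular net of spacing a on
  # a rhombic LxM tile, tetramers counted by wrapped distance search; solve
  # for the spacing whose tetramer density matches the inputs
  density_for <- function(a, L = 12, M = 12) {
    ij <- expand.grid(i = 0:(L - 1), j = 0:(M - 1))
    x <- a * (ij$i + ij$j / 2); y <- a * ij$j * sqrt(3) / 2
    u <- c(a * L, 0); v <- c(a * M / 2, a * M * sqrt(3) / 2)
    n <- length(x); cnt <- 0L
    for (p in seq_len(n - 1)) {
      dx0 <- x[(p + 1):n] - x[p]; dy0 <- y[(p + 1):n] - y[p]
      best <- rep(Inf, n - p)
      for (su in -1:1) for (sv in -1:1)
        best <- pmin(best, sqrt((dx0 + su * u[1] + sv * v[1])^2 +
                                  (dy0 + su * u[2] + sv * v[2])^2))
      cnt <- cnt + sum(abs(best - a) < 1e-6 * a)
    }
    cnt / (L * M * sqrt(3) / 2 * a^2)   # tetramers per nm^2
  }
  target <- 1e5 / 135e6
  f <- function(a) density_for(a) - target
  a_oracle <- uniroot(f, c(50, 90), tol = 1e-4)$root
  expect_equal(a_oracle, spectrin_length_from_density(1e5, 135),
               tolerance = 1e-3)
})

test_that("treadmilling turnover is linear in length and inverse in rate", {
  expect_equal(turnover_minutes(1000, 27.57, 0.3), 20.15, tolerance = 0.005)
  expect_equal(turnover_minutes(500, 27.57, 0.3),
               turnover_minutes(1000, 27.57, 0.3) / 2)
  expect_equal(turnover_minutes(1000, 27.57, 0.6),
               turnover_minutes(1000, 27.57, 0.3) / 2)
  expect_error(turnover_minutes(1000, 27.57, 0), "infinite")
})

test_that("surface amplification matches the closed form and a mesh oracle", {
  expect_equal(surface_amplification(120, 0, 1000), 1)
  expect_equal(surface_amplification(115, 50, 1000), 29.116,
               tolerance = 1e-3)
  expect_equal(surface_amplification(120, 50, 1000), 26.821,
               tolerance = 1e-3)
  a1 <- surface_amplification(120, 50, 1000, cap = "none") - 1
  a2 <- surface_amplification(120, 50, 2000, cap = "none") - 1
  expect_equal(a2 / a1, 2)
  expect_error(surface_amplification(90, 50, 1000), "overlap")

  # triangulated-mesh oracle for the lateral + cap area
  mesh <- membrane_surface(scene_spec(membrane_thickness = 5), n_theta = 96,
                           n_z = 60)$inner
  foot <- sqrt(3) / 2 * 120^2
  fold_mesh <- (foot + mesh_area(mesh) - pi * 50^2) / foot
  expect_equal(fold_mesh, surface_amplification(120, 50, 1000),
               tolerance = 0.005)
})

test_that("inter-microvillar gap spans the measured terminal-web distance", {
  expect_equal(intermicrovillar_gap(115, 55), 60)
  expect_equal(intermicrovillar_gap(120, 50), 70)
  expect_equal(intermicrovillar_gap(100, 100), 0)
  expect_error(intermicrovillar_gap(90, 100), "negative gap")
})

test_that("stoichiometry report counts placed instances per 10 actin", {
  xl <- small_crosslinkers()
  rep <- stoichiometry_report(xl)
  expect_equal(rep$n_actin, 19 * 39)
  cnt <- rep$counts
  expect_equal(cnt$count[cnt$component == "fimbrin"], 126L)
  expect_equal(cnt$per10[cnt$component == "fimbrin"], 10 * 126 / 741)
  expect_equal(cnt$per10[cnt$component == "villin"],
               saturation_stoichiometry(2, 13), tolerance = 1e-12)
})
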