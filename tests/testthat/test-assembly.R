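test_that("bundle construction counts and axial register", {
  b <- build_bundle(actin_sym(), hex_points(2, 120), 1000)
  expect_equal(b$n_monomers, 362L)
  expect_equal(nrow(b$lattice$points) * b$n_monomers, 6878L)

  # axial register: same z and same azimuthal phase on every filament
  for (i in c(0, 5, 361)) {
    tr <- lapply(c(1, 2, 19), function(f) site_transform(b, f, i))
    zs <- vapply(tr, function(t) t$t[3], numeric(1))
    expect_equal(zs, rep(i * 27.57, 3), tolerance = 1e-9)
    expect_lt(max(abs(tr[[1]]$R - tr[[2]]$R)), 1e-12)
    expect_lt(max(abs(tr[[1]]$R - tr[[3]]$R)), 1e-12)
  }

  one <- build_bundle(actin_sym(), hex_points(0, 120), 2.757)
  expect_equal(one$n_monomers, 1L)
  t0 <- site_transform(one, 1, 0)
  expect_equal(t0$R, diag(3), tolerance = 1e-12)
  expect_equal(t0$t, c(0, 0, 0))
  expect_error(build_bundle(actin_sym(), hex_points(2, 120), 0), "positive")
})

test_that("pose propagation follows the symmetry operators", {
  b <- repeat_bundle()
  ref <- rigid_transform(translation = c(10, 0, 0))
  # 13 monomers up: six full turns, azimuth unchanged (to twist rounding)
  p13 <- propagate_pose(ref, b, 1, 13)
  expect_equal(p13$t, c(10, 0, 358.41), tolerance = 1e-2)
  # adjacent filament, same monomer: same pose shifted by a lattice vector
  p1 <- propagate_pose(ref, b, 1, 5)
  p2 <- propagate_pose(ref, b, 2, 5)
  lat <- b$lattice$points[2, ] - b$lattice$points[1, ]
  expect_equal(p2$t - p1$t, c(unname(lat), 0), tolerance = 1e-9)
  expect_lt(max(abs(p1$R - p2$R)), 1e-12)
  expect_error(propagate_pose(ref, b, 1, 1000), "out of range")
  expect_error(propagate_pose(ref, b, 99, 0), "out of range")
})

test_that("candidate enumeration honours facing, linker and flexibility", {
  b <- repeat_bundle()
  fim <- surrogate_spec("fimbrin")
  classes <- levels(b$edges$class)
  by_class <- lapply(classes, function(cl) b$edges[b$edges$class == cl, ][1, ])
  names(by_class) <- classes

  for (cl in classes) {
    cands <- enumerate_crosslink_candidates(b, fim, by_class[[cl]], 0)
    expect_gte(length(cands), 1)
  }
  # a 1-degree cross-linker cannot serve the classes needing ~4.6 deg,
  # but still serves the (almost exactly achievable) third class
  expect_length(enumerate_crosslink_candidates(b, fim, by_class$d, 0,
                                               flexibility = 1), 0)
  expect_length(enumerate_crosslink_candidates(b, fim, by_class$f, 0,
                                               flexibility = 1), 0)
  expect_gte(length(enumerate_crosslink_candidates(b, fim, by_class$e, 0,
                                                   flexibility = 1)), 1)
  # a zero-length linker admits nothing
  fim0 <- fim
  fim0$linker_max <- 0
  expect_length(enumerate_crosslink_candidates(b, fim0, by_class$d, 0), 0)
  # incomplete repeat is skipped with a message, not an error
  expect_message(
    out <- enumerate_crosslink_candidates(b, fim, by_class$d, 99),
    "incomplete")
  expect_length(out, 0)
})

test_that("selection enforces polarity and breaks ties deterministically", {
  b <- repeat_bundle()
  fim <- surrogate_spec("fimbrin")
  edge <- b$edges[b$edges$class == "d", ][1, ]
  cands <- enumerate_crosslink_candidates(b, fim, edge, 0)
  genuine <- select_crosslink(cands, fim)
  d <- genuine$domains[order(genuine$domains$rank), ]
  expect_gt(d$z[1], d$z[2])   # rank 1 toward the pointed (+z) end

  # a reciprocal-like candidate (domain heights swapped) is a hard reject
  fake <- genuine
  fake$domains$z <- rev(fake$domains$z)
  expect_error(select_crosslink(list(fake), fim), "polarity")
  kept <- select_crosslink(list(fake, genuine), fim)
  expect_equal(kept$domains$monomer, genuine$domains$monomer)
  # order of the candidate list does not matter
  kept2 <- select_crosslink(rev(list(fake, genuine)), fim)
  expect_identical(kept, kept2)
})

test_that("full cross-linker placement saturates every edge and repeat", {
  xl <- small_crosslinkers()
  p <- xl$placements
  expect_equal(length(unique(p[p$component == "fimbrin", ]$instance)), 126L)
  expect_equal(length(unique(p[p$component == "villin", ]$instance)), 126L)

  r1 <- p[p$rank == 1, ]
  # one unique binding level per direction class per species
  lev <- tapply(r1$monomer %% 13, list(r1$component, r1$class), unique)
  expect_equal(as.numeric(lev["fimbrin", c("d", "e", "f")]), c(1, 5, 9))
  expect_equal(as.numeric(lev["villin", c("d", "e", "f")]), c(10, 1, 5))
  # placements of one class share their level to within one monomer rise
  for (sp in c("fimbrin", "villin")) for (cl in c("d", "e", "f")) {
    zz <- r1[r1$component == sp & r1$class == cl & r1$repeat_index == 1, ]$z
    expect_lte(diff(range(zz)), 27.57 + 1e-9)
  }
  # fimbrin and villin are vertically staggered on every edge
  key <- paste(p$edge_a, p$edge_b, p$repeat_index)
  for (k in unique(key)[1:30]) {
    mf <- p[key == k & p$component == "fimbrin", ]$monomer
    mv <- p[key == k & p$component == "villin", ]$monomer
    expect_length(intersect(mf, mv), 0)
  }
})

test_that("a bundle shorter than one repeat takes no cross-linkers", {
  b <- build_bundle(actin_sym(), hex_points(2, 120), 30)  # 10 monomers
  xl <- place_all_crosslinkers(b)
  expect_equal(nrow(xl$placements), 0L)
})

test_that("myosin decorates outer filaments two per repeat plus one per turn", {
  b <- repeat_bundle()
  xl <- small_crosslinkers()
  mo <- place_myosin(b, crosslinkers = xl)
  m <- mo$placements
  # outer-ring filaments only, radially outward
  expect_true(all(b$lattice$ring[m$filament] == 2L))
  expect_true(all(m$dev <= 30))
  reg <- m[m$extra == FALSE, ]
  tab <- table(reg$filament, reg$monomer %/% 13)
  expect_equal(dim(tab), c(12L, 3L))
  expect_true(all(tab == 2L))
  ext <- m[m$extra == TRUE, ]
  expect_equal(nrow(ext), 1L)   # one full 360-degree turn in 3 repeats
  expect_equal(nrow(m), 12L * 3L * 2L + 1L)

  # unreachable extension threshold: nothing placed
  none <- suppressWarnings(place_myosin(b, min_radial_extension = 1e4))
  expect_equal(nrow(none$placements), 0L)
})

test_that("adjacent outer filaments step one long-pitch monomer", {
  b <- repeat_bundle()
  m <- place_myosin(b)$placements
  outer <- which(b$lattice$ring == 2L)
  az <- (atan2(b$lattice$points[outer, 2],
               b$lattice$points[outer, 1]) * 180 / pi) %% 360
  ord <- outer[order(az)]
  for (k in seq_along(ord)) {
    f <- ord[k]; g <- ord[if (k == length(ord)) 1L else k + 1L]
    dm <- outer(m[m$filament == g, ]$monomer, m[m$filament == f, ]$monomer,
                "-")
    expect_true(2 %in% dm)   # one long-helix monomer = 2 genetic indices
  }
})

test_that("light chains ride the neck three per motor", {
  b <- repeat_bundle()
  mo <- place_myosin(b)
  lc <- attach_light_chains(mo)
  expect_equal(nrow(lc$placements), 3L * nrow(mo$placements))
  # collinear along the neck axis
  for (mi in unique(lc$placements$motor_instance)[1:5]) {
    pp <- as.matrix(lc$placements[lc$placements$motor_instance == mi,
                                  c("x", "y", "z")])
    v1 <- pp[2, ] - pp[1, ]; v2 <- pp[3, ] - pp[1, ]
    cr <- c(v1[2] * v2[3] - v1[3] * v2[2], v1[3] * v2[1] - v1[1] * v2[3],
            v1[1] * v2[2] - v1[2] * v2[1])
    expect_lt(sqrt(sum(cr^2)), 1e-6)
  }
  none <- suppressWarnings(place_myosin(b, min_radial_extension = 1e4))
  expect_equal(nrow(attach_light_chains(none)$placements), 0L)
})

test_that("motor anchors trace a right-handed double-helical barber pole", {
  b <- repeat_bundle()
  mo <- place_myosin(b)
  bp <- barber_pole_parameters(mo)
  expect_equal(bp$n_strands, 2L)
  # pitch of the long-pitch (two-start) actin helix: 26 monomers
  expect_equal(bp$pitch, 26 * 27.57, tolerance = 0.01)
  expect_equal(bp$handedness, "right")
  # 13 long-pitch steps spread over the 12 outer filaments per turn
  expect_equal(bp$rise_per_filament_step, 26 * 27.57 / 12, tolerance = 0.01)

  # a single motor cannot define the helix
  one <- mo
  one$placements <- mo$placements[1, ]
  expect_error(barber_pole_parameters(one), "too few")
})

test_that("clash detection matches the all-pairs oracle", {
  # random soup with genuine overlaps
  set.seed(7)
  n <- 80
  soup <- data.frame(component = "blob", instance = seq_len(n), label = "B",
                     x = runif(n, 0, 300), y = runif(n, 0, 300),
                     z = runif(n, 0, 300), r = runif(n, 10, 30), mass = 1)
  fast <- detect_clashes(soup)
  slow <- brute_force_clashes(soup)
  expect_gt(nrow(fast), 0)
  expect_equal(pair_key(fast), pair_key(slow))
  # order independence
  fast2 <- detect_clashes(soup[sample(n), ])
  expect_equal(pair_key(fast2), pair_key(fast))
  # two coincident beads of distinct components: exactly one clash
  two <- data.frame(component = c("a", "b"), instance = 1L, label = "X",
                    x = 0, y = 0, z = 0, r = 5, mass = 1)
  expect_equal(nrow(detect_clashes(two)), 1L)
})

test_that("the placed model is clash-free (staggered cross-links)", {
  b7 <- repeat_bundle(rings = 1, repeats = 2)
  xl7 <- place_all_crosslinkers(b7)
  beads <- rbind(placement_beads(b7), placement_beads(xl7))
  fast <- detect_clashes(beads)
  slow <- brute_force_clashes(beads)
  expect_equal(nrow(fast), 0L)
  expect_equal(nrow(slow), 0L)
  # fimbrin vs villin on the full 19-filament test bundle: no contacts
  xl <- small_crosslinkers()
  expect_equal(nrow(detect_clashes(xl)), 0L)
})
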