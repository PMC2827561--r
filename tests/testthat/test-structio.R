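test_that("assemblies round-trip through mmCIF and PDB at format precision", {
  b <- repeat_bundle(rings = 1, repeats = 1)
  bb <- bundle_beads(b)
  cif <- withr::local_tempfile(fileext = ".cif")
  write_assembly(b, cif)
  s <- read_structure(cif)
  expect_equal(nrow(s$atoms), nrow(bb))
  expect_lt(max(abs(s$atoms$x - bb$x), abs(s$atoms$y - bb$y),
                abs(s$atoms$z - bb$z)), 1e-3)
  # chains: one per component instance (filament)
  expect_equal(length(unique(s$atoms$chain)), 7L)
  # write what was read: coordinates survive a second round trip
  cif2 <- withr::local_tempfile(fileext = ".cif")
  write_assembly(s, cif2)
  s2 <- read_structure(cif2)
  expect_equal(s2$atoms$x, s$atoms$x, tolerance = 1e-9)

  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_assembly(b, pdb, format = "pdb")
  sp <- read_structure(pdb)
  expect_lt(max(abs(sp$atoms$x - bb$x), abs(sp$atoms$z - bb$z)), 1e-3)
})

test_that("cross-link chains are distinct and strict PDB enforces its limit", {
  b <- repeat_bundle(rings = 1, repeats = 2)
  xl <- place_all_crosslinkers(b)
  cif <- withr::local_tempfile(fileext = ".cif")
  write_assembly(xl, cif)
  s <- read_structure(cif)
  n_inst <- length(unique(xl$placements[xl$placements$component ==
                                          "fimbrin", ]$instance)) +
    length(unique(xl$placements[xl$placements$component ==
                                  "villin", ]$instance))
  expect_equal(length(unique(s$atoms$chain)), n_inst)
  # more than 62 component instances must refuse strict PDB mode
  expect_error(write_assembly(small_crosslinkers(),
                              withr::local_tempfile(fileext = ".pdb"),
                              format = "pdb"), "mmCIF")
  expect_error(write_assembly(list(), withr::local_tempfile()), "empty")
})

test_that("malformed structure files raise parse errors with context", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HEADER  test", "ATOM      1  CA  ALA A   1      11.1"), p)
  expect_error(read_structure(p), "truncated")
  writeLines("HEADER only", p)
  expect_error(read_structure(p), "no ATOM/HETATM")
  q <- withr::local_tempfile(fileext = ".cif")
  writeLines(c("data_x", "loop_", "_foo.bar", "1"), q)
  expect_error(read_structure(q), "atom_site")
  expect_error(read_structure("does-not-exist.pdb"), "no such file")
})

test_that("superposition recovers known transforms exactly", {
  set.seed(3)
  P <- matrix(rnorm(150, sd = 20), ncol = 3)
  R <- rot_z(141.7) %*% rot_x(-33.9)
  Q <- sweep(P %*% t(R), 2, -c(5, -8, 13))
  fit <- superpose(P, Q)
  expect_lt(max(abs(fit$transform$R - R)), 1e-9)
  expect_lt(fit$rmsd, 1e-9)
  moved <- rt_apply(fit$transform, P)
  expect_lt(max(abs(moved - Q)), 1e-9)

  # identical sets: identity transform
  fit0 <- superpose(P, P)
  expect_lt(max(abs(fit0$transform$R - diag(3))), 1e-9)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-12)
})

test_that("superposition RMSD is invariant under rigid pre-transforms", {
  set.seed(4)
  P <- matrix(rnorm(90, sd = 15), ncol = 3)
  Q <- P + matrix(rnorm(90, sd = 0.8), ncol = 3)
  r1 <- superpose(P, Q)$rmsd
  pre <- rigid_transform(rot_z(77) %*% rot_x(12), c(100, -4, 9))
  r2 <- superpose(rt_apply(pre, P), Q)$rmsd
  expect_equal(r1, r2, tolerance = 1e-9)
  # noise calibration: rmsd ~ sigma * sqrt(3) for isotropic noise
  set.seed(5)
  P2 <- matrix(rnorm(1500, sd = 30), ncol = 3)
  Q2 <- P2 + matrix(rnorm(1500, sd = 0.5), ncol = 3)
  expect_equal(superpose(P2, Q2)$rmsd, 0.5 * sqrt(3), tolerance = 0.1)
})

test_that("superposition agrees with an independent reference fit", {
  set.seed(6)
  P <- matrix(rnorm(120, sd = 10), ncol = 3)
  R <- rot_x(25) %*% rot_z(-100)
  Q <- sweep(P %*% t(R), 2, -c(1, 2, 3))
  ours <- rt_apply(superpose(P, Q)$transform, P)
  # independent route: bio3d least-squares fit on interleaved xyz vectors
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  ref <- matrix(bio3d::rot.lsq(as.vector(t(Pc)), as.vector(t(Qc))),
                ncol = 3, byrow = TRUE)
  ref <- sweep(ref, 2, -colMeans(Q))
  expect_lt(max(abs(ours - ref)), 1e-6)
})

test_that("degenerate point sets are rejected", {
  expect_error(superpose(matrix(rnorm(6), 2), matrix(rnorm(6), 2)),
               "at least 3")
  line <- cbind(1:5, 2 * (1:5), -1:3 * 0)
  expect_error(superpose(line, line), "collinear")
  expect_error(superpose(matrix(0, 4, 3), matrix(rnorm(9), 3)), "paired")
})

test_that("fixtures are pure functions of component and seed", {
  a1 <- make_fixture("actin", 0)
  a2 <- make_fixture("actin", 0)
  expect_identical(a1$structure$atoms, a2$structure$atoms)
  expect_identical(a1$beads, a2$beads)
  a3 <- make_fixture("actin", 1)
  expect_false(identical(a1$structure$atoms, a3$structure$atoms))
  expect_error(make_fixture("ezrin"), "arg")

  v <- make_fixture("villin", 2)
  expect_equal(length(v$spec$domains), 2L)       # two actin-binding domains
  expect_equal(v$spec$role, "crosslinker")
  m <- make_fixture("myosin", 2)
  expect_equal(nrow(m$spec$iq_frames), 3L)       # three light-chain frames
  # pseudo-atoms stay inside the bead envelope
  env_ok <- sapply(seq_len(nrow(v$beads)), function(k)
    any(sqrt((v$structure$atoms$x - v$beads$x[k])^2 +
               (v$structure$atoms$y - v$beads$y[k])^2 +
               (v$structure$atoms$z - v$beads$z[k])^2) <= v$beads$r[k]))
  expect_true(all(env_ok))
  # fixture structures round-trip through PDB
  p <- withr::local_tempfile(fileext = ".pdb")
  write_assembly(m$structure, p, format = "pdb")
  rt <- read_structure(p)
  expect_equal(rt$atoms$x, m$structure$atoms$x, tolerance = 1e-3)
})
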