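#' Brush-border scene specification
#'
#' Dimensions of the in-situ scene, all in nm, defaulting to the murine
#' brush-border values: microvilli 1000 nm long, 50 nm radius, membrane
#' 5 nm thick, hexagonally packed at 115-120 nm (default 120), with 65 nm
#' spectrin tetramers in the terminal web. Spectrin helix pitch and radius
#' are free parameters of the coarse double-helix path (defaults 13 nm and
#' 3 nm give a smooth rod).
#'
#' @param mv_length,mv_radius,membrane_thickness,mv_spacing Microvillus
#'   geometry, nm.
#' @param n_microvilli Number of microvilli in the scene.
#' @param spectrin_length Tetramer end-to-end length, nm.
#' @param spectrin_pitch,spectrin_radius Coarse double-helix parameters, nm.
#' @param spectrin_per_pair Tetramers per adjacent microvillus pair.
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(mv_length = 1000, mv_radius = 50,
                       membrane_thickness = 5, mv_spacing = 120,
                       n_microvilli = 7, spectrin_length = 65,
                       spectrin_pitch = 13, spectrin_radius = 3,
                       spectrin_per_pair = 2) {
  if (any(c(mv_length, mv_radius, membrane_thickness, mv_spacing,
            spectrin_length, spectrin_pitch, spectrin_radius) <= 0))
    stop("all scene dimensions must be positive")
  if (mv_spacing <= 2 * mv_radius)
    stop("microvilli overlap: spacing must exceed twice the radius")
  if (n_microvilli < 1) stop("need at least one microvillus")
  structure(as.list(environment()), class = "scene_spec")
}

#' Triangulated microvillar membrane surface
#'
#' Cylinder plus hemispherical cap for one microvillus, as inner and outer
#' leaflets separated by the membrane thickness (a zero thickness gives a
#' single surface). Mesh areas converge to the closed-form areas as the
#' resolution grows.
#'
#' @param spec A [scene_spec()].
#' @param n_theta Azimuthal divisions.
#' @param n_z Axial divisions of the cylindrical part.
#' @return List of meshes (`inner`, `outer`), each with `vertices` (n x 3,
#'   nm) and `faces` (m x 3 vertex indices).
#' @export
membrane_surface <- function(spec, n_theta = 48, n_z = 40) {
  stopifnot(inherits(spec, "scene_spec"))
  if (spec$mv_radius <= 0) stop("degenerate membrane: zero radius")
  one <- function(r) capped_cylinder_mesh(r, spec$mv_length, n_theta, n_z)
  if (spec$membrane_thickness == 0) return(list(inner = one(spec$mv_radius)))
  list(inner = one(spec$mv_radius),
       outer = one(spec$mv_radius + spec$membrane_thickness))
}

capped_cylinder_mesh <- function(radius, length, n_theta, n_z) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  zs <- seq(0, length, length.out = n_z + 1)
  ring <- cbind(cos(th), sin(th))
  verts <- do.call(rbind, lapply(zs, function(z)
    cbind(radius * ring, z)))
  # hemispherical cap on top (phi from equator to pole)
  n_phi <- max(4L, n_theta %/% 4L)
  phis <- seq(0, pi / 2, length.out = n_phi + 1)[-1]
  for (ph in phis[-n_phi])
    verts <- rbind(verts, cbind(radius * cos(ph) * ring,
                                length + radius * sin(ph)))
  verts <- rbind(verts, c(0, 0, length + radius))
  nv <- nrow(verts)
  faces <- list()
  band <- function(a, b) {
    # quad band between vertex rings starting at a and b (1-based offsets)
    i <- 0:(n_theta - 1); j <- (i + 1) %% n_theta
    rbind(cbind(a + i, a + j, b + i), cbind(a + j, b + j, b + i))
  }
  n_rings <- n_z + 1 + (n_phi - 1)
  for (k in seq_len(n_rings - 1))
    faces[[k]] <- band((k - 1) * n_theta + 1, k * n_theta + 1)
  apex <- nv
  top0 <- (n_rings - 1) * n_theta + 1
  i <- 0:(n_theta - 1); j <- (i + 1) %% n_theta
  faces[[length(faces) + 1]] <- cbind(top0 + i, top0 + j, apex)
  list(vertices = verts, faces = do.call(rbind, faces))
}

#' Total area of a triangle mesh
#'
#' @param mesh List with `vertices` and `faces`.
#' @return Area in squared mesh units.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], ] - v[f[, 1], ]
  b <- v[f[, 3], ] - v[f[, 1], ]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Assemble a hexagonal microvillus array
#'
#' Rigidly copies a core-bundle bead model onto hexagonal microvillus
#' centers. In situ the barbed (plus) ends face the microvillar tip, so the
#' bundle template (built pointed-up) is flipped to barbed-up before
#' copying; each copy is identical up to translation.
#'
#' @param spec A [scene_spec()].
#' @param bundle An `actin_bundle` used as the template (default: the
#'   19-filament core bundle at the scene length).
#' @return Object of class `brush_border_scene`: list with `spec`,
#'   `centers` (nm), `bundle_template` beads (nm, barbed-up, base at z = 0)
#'   and `bundle_radius_nm`.
#' @export
microvillus_array <- function(spec, bundle = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  if (is.null(bundle))
    bundle <- build_bundle(make_symmetry(27.57, -166.154), hex_points(2, 120),
                           spec$mv_length, polarity = "barbed_up")
  rad_nm <- max(bundle_radius(bundle$lattice, 30,
                              seq(0, 359, by = 5))) / 10
  if (spec$mv_spacing < 2 * rad_nm)
    stop("bundles overlap: spacing below the bundle diameter")
  rings_needed <- 0
  while (3 * rings_needed^2 + 3 * rings_needed + 1 < spec$n_microvilli)
    rings_needed <- rings_needed + 1
  centers <- hex_points(rings_needed, spec$mv_spacing)$points
  centers <- centers[seq_len(spec$n_microvilli), , drop = FALSE]
  beads <- bundle_beads(bundle)
  bb <- data.table::copy(beads)
  # flip to barbed-up (rotate pi about x), rebase to z = 0, convert to nm
  bb[, `:=`(y = -y / 10, z = -z / 10, x = x / 10, r = r / 10)]
  bb[, z := z - min(z)]
  structure(list(spec = spec, centers = centers, bundle_template = bb,
                 bundle_radius_nm = rad_nm),
            class = "brush_border_scene")
}

#' @export
print.brush_border_scene <- function(x, ...) {
  cat(sprintf(
    "brush-border scene: %d microvilli, spacing %.0f nm, bundle radius %.1f nm\n",
    nrow(x$centers), x$spec$mv_spacing, x$bundle_radius_nm))
  invisible(x)
}

#' All bundle beads of a scene, in nm
#'
#' @param scene A [microvillus_array()] scene.
#' @return Bead table with microvillus index in `instance`.
#' @export
scene_beads <- function(scene) {
  stopifnot(inherits(scene, "brush_border_scene"))
  out <- lapply(seq_len(nrow(scene$centers)), function(k) {
    b <- data.table::copy(scene$bundle_template)
    b[, `:=`(x = x + scene$centers[k, 1],
             y = y + scene$centers[k, 2])]
    b[, `:=`(component = paste0("mv", k, "_", component))]
    b
  })
  data.table::rbindlist(out)
}

#' Coarse spectrin terminal web
#'
#' Links every adjacent microvillus pair with coarse spectrin tetramer
#' paths: antiparallel double helices of beads whose end-to-end distance is
#' the spectrin length (65 nm), bridging the inter-bundle gap near the
#' bundle bases. Warns when the gap is so small that the web would be
#' compressed below half the tetramer length.
#'
#' @param scene A [microvillus_array()] scene with >= 2 microvilli.
#' @param n_beads Beads per strand.
#' @return data.table of spectrin beads (nm) with pair and tetramer ids;
#'   `attr(,"pairs")` holds the adjacency table and the bridged gap.
#' @export
terminal_web <- function(scene, n_beads = 24) {
  stopifnot(inherits(scene, "brush_border_scene"))
  sp <- scene$spec
  n <- nrow(scene$centers)
  if (n < 2) stop("terminal web needs at least 2 microvilli")
  d <- as.matrix(stats::dist(scene$centers))
  pairs <- which(upper.tri(d) & abs(d - sp$mv_spacing) <
                   1e-6 * sp$mv_spacing, arr.ind = TRUE)
  gap <- sp$mv_spacing - 2 * scene$bundle_radius_nm
  if (gap < 0.5 * sp$spectrin_length)
    warning(sprintf(
      "compressed terminal web: gap %.1f nm < half the spectrin length", gap))
  L <- sp$spectrin_length
  out <- list()
  tet <- 0L
  for (p in seq_len(nrow(pairs))) {
    a <- scene$centers[pairs[p, 1], ]; b <- scene$centers[pairs[p, 2], ]
    e <- (b - a) / sqrt(sum((b - a)^2))
    perp <- c(-e[2], e[1])
    mid <- (a + b) / 2
    for (k in seq_len(sp$spectrin_per_pair)) {
      tet <- tet + 1L
      z0 <- 10 + 20 * (k - 1)              # attachment rings near the base
      t <- seq(-L / 2, L / 2, length.out = n_beads)
      phase <- 2 * pi * t / sp$spectrin_pitch
      for (s in 1:2) {                     # antiparallel strand pair
        ph <- phase + if (s == 1) 0 else pi
        out[[length(out) + 1L]] <- data.table::data.table(
          component = "spectrin", instance = tet, strand = s,
          label = "SPC",
          x = mid[1] + e[1] * t + perp[1] * sp$spectrin_radius * cos(ph),
          y = mid[2] + e[2] * t + perp[2] * sp$spectrin_radius * cos(ph),
          z = z0 + sp$spectrin_radius * sin(ph),
          r = 1, mass = 12000, pair = p)
      }
    }
  }
  res <- data.table::rbindlist(out)
  attr(res, "pairs") <- data.table::data.table(
    a = pairs[, 1], b = pairs[, 2], gap_nm = gap)
  res
}

#' Export a mesh as Wavefront OBJ
#'
#' @param mesh List with `vertices` and `faces`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  writeLines(c(sprintf("v %.6g %.6g %.6g", v[, 1], v[, 2], v[, 3]),
               sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])), path)
  invisible(path)
}

#' Export scene beads as a coordinates table (TSV)
#'
#' @param beads A bead table (nm or A, as produced).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bead_tsv <- function(beads, path) {
  utils::write.table(beads, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
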