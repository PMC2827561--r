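#' Build a unipolar, axially registered filament bundle
#'
#' Places one helically symmetric filament on every lattice point by pure
#' x-y translation, so all filaments share the same polarity and the same
#' azimuthal phase at every z (axial register). Site (f, i) then carries the
#' transform `translate(lattice point f) o monomer_transform(i)`, and a
#' component pose defined once against the canonical monomer can be
#' propagated to any site ([propagate_pose()]).
#'
#' @param sym A [make_symmetry()] object (e.g. 13/6 actin).
#' @param lattice A [hex_points()] object.
#' @param length_nm Filament length in nm; the monomer count per filament is
#'   `floor(length_nm * 10 / rise)` (1000 nm of 27.57 A actin gives 362).
#' @param polarity `"pointed_up"` (default; pointed/minus end toward +z, the
#'   convention of the model figures) or `"barbed_up"` (the in-situ
#'   orientation, barbed ends at the microvillar tip). Site transforms are
#'   always constructed pointed-up; the flip is applied by scene assembly
#'   and export.
#' @return An object of class `actin_bundle`.
#' @examples
#' b <- build_bundle(make_symmetry(27.57, -166.154), hex_points(2, 120), 100)
#' b$n_monomers
#' @export
build_bundle <- function(sym, lattice, length_nm = 1000,
                         polarity = c("pointed_up", "barbed_up")) {
  stopifnot(inherits(sym, "helical_symmetry"), inherits(lattice, "hex_lattice"))
  polarity <- match.arg(polarity)
  if (!is.numeric(length_nm) || length_nm <= 0)
    stop("'length_nm' must be positive")
  if (nrow(lattice$points) < 1) stop("lattice has no filaments")
  n_mon <- as.integer(floor(length_nm * 10 / sym$rise))
  if (n_mon < 1) stop("bundle shorter than one monomer rise")
  structure(list(sym = sym, lattice = lattice,
                 n_monomers = n_mon, polarity = polarity,
                 edges = adjacency_edges(lattice)),
            class = "actin_bundle")
}

#' @export
print.actin_bundle <- function(x, ...) {
  cat(sprintf(
    "actin bundle: %d filaments x %d monomers (%d sites), %s\n",
    nrow(x$lattice$points), x$n_monomers,
    nrow(x$lattice$points) * x$n_monomers, x$polarity))
  print(x$sym)
  invisible(x)
}

#' Transform of a bundle site
#'
#' @param bundle An [build_bundle()] object.
#' @param filament Filament index (1-based lattice point index).
#' @param i Monomer index (0-based along the filament).
#' @return A [rigid_transform()] taking canonical-monomer coordinates to the
#'   site.
#' @export
site_transform <- function(bundle, filament, i) {
  stopifnot(inherits(bundle, "actin_bundle"))
  if (filament < 1 || filament > nrow(bundle$lattice$points))
    stop("filament index out of range")
  if (i < 0 || i >= bundle$n_monomers)
    stop("monomer index out of range [0, ", bundle$n_monomers - 1, "]")
  p <- bundle$lattice$points[filament, ]
  rt_compose(rigid_transform(translation = c(p[1], p[2], 0)),
             monomer_transform(bundle$sym, i))
}

#' Propagate a reference pose to a bundle site
#'
#' Applies the site transform to a pose defined relative to the canonical
#' monomer at the origin: the symmetry-propagation step that positions every
#' copy of a component from a single reference placement.
#'
#' @param reference_pose A [rigid_transform()] relative to the canonical
#'   monomer.
#' @inheritParams site_transform
#' @return A [rigid_transform()] in bundle coordinates.
#' @export
propagate_pose <- function(reference_pose, bundle, filament, i) {
  stopifnot(inherits(reference_pose, "rigid_transform"))
  rt_compose(site_transform(bundle, filament, i), reference_pose)
}

# ---- placements -----------------------------------------------------------

# A placement set holds one row per placed *domain*:
#   component, instance, domain, rank, filament, monomer, class,
#   px, py (filament axis, A), ang (site rotation, deg), z0 (site z, A),
#   x, y, z (domain anchor, world A), dev (facing deviation, deg)
new_placement_set <- function(rows, specs, bundle) {
  if (!nrow(rows) || !"component" %in% names(rows))
    rows <- data.table::data.table(
      component = character(), instance = integer(), domain = character(),
      rank = integer(), filament = integer(), monomer = integer(),
      class = character(), px = numeric(), py = numeric(),
      ang = numeric(), z0 = numeric(), x = numeric(), y = numeric(),
      z = numeric(), dev = numeric())
  structure(list(placements = rows, specs = specs, bundle = bundle),
            class = "placement_set")
}

#' @export
print.placement_set <- function(x, ...) {
  p <- x$placements
  if (!nrow(p)) { cat("empty placement set\n"); return(invisible(x)) }
  tab <- p[, .(instances = length(unique(instance))), by = component]
  cat("placement set:\n")
  for (k in seq_len(nrow(tab)))
    cat(sprintf("  %-12s %5d\n", tab$component[k], tab$instances[k]))
  invisible(x)
}

#' Combine placement sets
#'
#' @param ... `placement_set` objects sharing a bundle.
#' @param deparse.level Unused (S3 signature).
#' @return A `placement_set`.
#' @export
rbind.placement_set <- function(..., deparse.level = 1) {
  sets <- list(...)
  rows <- data.table::rbindlist(lapply(sets, `[[`, "placements"),
                                fill = TRUE)
  specs <- do.call(c, lapply(sets, `[[`, "specs"))
  specs <- specs[!duplicated(names(specs))]
  new_placement_set(rows, specs, sets[[1]]$bundle)
}

#' Expand placements (or a bundle) into a coarse bead table
#'
#' @param x A `placement_set`, or an `actin_bundle` (one bead per monomer
#'   from the actin surrogate spec).
#' @param actin_spec Component spec used for bundle monomer beads.
#' @return A data.table with columns `component`, `instance`, `label`,
#'   `x`, `y`, `z` (A), `r` (A), `mass` (Da).
#' @export
placement_beads <- function(x, actin_spec = surrogate_spec("actin")) {
  if (inherits(x, "actin_bundle")) return(bundle_beads(x, actin_spec))
  stopifnot(inherits(x, "placement_set"))
  p <- x$placements
  if (!nrow(p))
    return(data.table::data.table(
      component = character(), instance = integer(), label = character(),
      x = numeric(), y = numeric(), z = numeric(), r = numeric(),
      mass = numeric()))
  out <- vector("list", 0L)
  for (comp in unique(p$component)) {
    spec <- x$specs[[comp]]
    for (domname in unique(p[component == comp]$domain)) {
      rows <- p[component == comp & domain == domname]
      dmc <- domain_monomer_coords(spec$domains[[domname]])
      bd <- spec$domains[[domname]]$beads
      th <- rows$ang * pi / 180
      co <- cos(th); si <- sin(th)
      for (k in seq_len(nrow(bd))) {
        bx <- dmc$beads[k, 1]; by <- dmc$beads[k, 2]; bz <- dmc$beads[k, 3]
        out[[length(out) + 1L]] <- data.table::data.table(
          component = comp, instance = rows$instance,
          label = bd$label[k],
          x = rows$px + bx * co - by * si,
          y = rows$py + bx * si + by * co,
          z = rows$z0 + bz,
          r = bd$r[k], mass = bd$mass[k])
      }
    }
  }
  data.table::rbindlist(out)[order(component, instance, label)]
}

#' @rdname placement_beads
#' @param bundle An `actin_bundle`.
#' @export
bundle_beads <- function(bundle, actin_spec = surrogate_spec("actin")) {
  stopifnot(inherits(bundle, "actin_bundle"))
  bd <- actin_spec$domains[[1]]$beads[1, ]
  np <- nrow(bundle$lattice$points)
  i <- rep(0:(bundle$n_monomers - 1), times = np)
  f <- rep(seq_len(np), each = bundle$n_monomers)
  data.table::data.table(
    component = "actin", instance = f, label = bd$label,
    x = bundle$lattice$points[f, 1], y = bundle$lattice$points[f, 2],
    z = i * bundle$sym$rise, r = bd$r, mass = bd$mass)
}

# ---- cross-linker placement ----------------------------------------------

#' Enumerate cross-link candidates on one edge and repeat
#'
#' Considers every assignment of the two binding domains to the two
#' filaments of an edge and every monomer pair inside the 13-monomer repeat
#' window, and keeps combinations where (a) each domain's binding surface
#' faces the partner filament to within the flexibility bound (by default
#' the worst-case hexagonal mismatch of the filament symmetry), (b) the two
#' domains' attach points are within the spec's linker separation limit, and
#' (c) every bead projects between the two filament axes.
#'
#' @param bundle An [build_bundle()] object with a closed symmetry.
#' @param spec A cross-linker [component_spec()].
#' @param edge One row of `bundle$edges` (see [adjacency_edges()]).
#' @param repeat_index 0-based repeat index; the window is monomers
#'   `[u * repeat_index, u * repeat_index + u - 1]`.
#' @param flexibility Facing bound in degrees; default
#'   `hexagonal_mismatch(bundle$sym)$max_deviation`.
#' @param between_tol Slack (A) for the between-the-filaments projection.
#' @return List of candidate placements (possibly empty; an incomplete
#'   repeat is skipped with a message). Each candidate is a list with the
#'   component name, edge, repeat, direction class, and a per-domain
#'   data.frame of bound sites and anchor positions.
#' @export
enumerate_crosslink_candidates <- function(bundle, spec, edge, repeat_index,
                                           flexibility = NULL,
                                           between_tol = 5) {
  stopifnot(inherits(bundle, "actin_bundle"),
            inherits(spec, "component_spec"))
  if (spec$role != "crosslinker") stop("'spec' must be a cross-linker")
  if (!has_closure(bundle$sym))
    stop("bundle symmetry has no repeat closure")
  u <- bundle$sym$units_per_repeat
  win <- (u * repeat_index):(u * repeat_index + u - 1)
  if (min(win) < 0 || max(win) >= bundle$n_monomers) {
    message(sprintf(
      "repeat %d incomplete on this bundle (%d monomers/filament); skipped",
      repeat_index, bundle$n_monomers))
    return(list())
  }
  if (is.null(flexibility))
    flexibility <- hexagonal_mismatch(bundle$sym)$max_deviation
  tw <- bundle$sym$twist; rise <- bundle$sym$rise
  ia <- edge$a; ib <- edge$b
  pa <- bundle$lattice$points[ia, ]; pb <- bundle$lattice$points[ib, ]
  L <- sqrt(sum((pb - pa)^2))
  ev <- (pb - pa) / L
  bond_ab <- (atan2(pb[2] - pa[2], pb[1] - pa[1]) * 180 / pi) %% 360
  doms <- spec$domains
  dmc <- lapply(doms, domain_monomer_coords)
  cands <- list()
  for (assign in 1:2) {
    fil <- if (assign == 1) c(ia, ib) else c(ib, ia)
    porg <- if (assign == 1) list(pa, pb) else list(pb, pa)
    bond <- if (assign == 1) c(bond_ab, (bond_ab + 180) %% 360)
            else c((bond_ab + 180) %% 360, bond_ab)
    adm <- lapply(1:2, function(d) {
      dev <- circ_dist(doms[[d]]$azimuth + win * tw, bond[d], 360)
      list(i = win[dev <= flexibility], dev = dev[dev <= flexibility])
    })
    if (!length(adm[[1]]$i) || !length(adm[[2]]$i)) next
    for (k1 in seq_along(adm[[1]]$i)) for (k2 in seq_along(adm[[2]]$i)) {
      ii <- c(adm[[1]]$i[k1], adm[[2]]$i[k2])
      world <- lapply(1:2, function(d) {
        th <- ii[d] * tw * pi / 180
        R2 <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
        shift <- c(porg[[d]], 0) + c(0, 0, ii[d] * rise)
        rot3 <- function(v) c(R2 %*% v[1:2], v[3])
        list(anchor = rot3(dmc[[d]]$anchor) + shift,
             attach = rot3(dmc[[d]]$attach) + shift,
             beads = t(apply(dmc[[d]]$beads, 1, rot3)) +
               rep(shift, each = nrow(dmc[[d]]$beads)))
      })
      sep <- sqrt(sum((world[[1]]$attach - world[[2]]$attach)^2))
      if (sep > spec$linker_max) next
      tproj <- (rbind(world[[1]]$beads, world[[2]]$beads)[, 1:2] -
                  rep(pa, each = nrow(world[[1]]$beads) +
                        nrow(world[[2]]$beads))) %*% ev
      if (min(tproj) < -between_tol || max(tproj) > L + between_tol) next
      cands[[length(cands) + 1L]] <- list(
        component = spec$name,
        edge = c(a = ia, b = ib), repeat_index = repeat_index,
        class = as.character(edge$class),
        separation = sep,
        t_range = range(tproj), edge_length = L,
        domains = data.frame(
          domain = names(doms),
          rank = vapply(doms, `[[`, integer(1), "polarity_rank"),
          filament = fil, monomer = ii,
          px = c(porg[[1]][1], porg[[2]][1]),
          py = c(porg[[1]][2], porg[[2]][2]),
          ang = ii * tw, z0 = ii * rise,
          x = c(world[[1]]$anchor[1], world[[2]]$anchor[1]),
          y = c(world[[1]]$anchor[2], world[[2]]$anchor[2]),
          z = c(world[[1]]$anchor[3], world[[2]]$anchor[3]),
          dev = c(circ_dist(doms[[1]]$azimuth + ii[1] * tw, bond[1], 360),
                  circ_dist(doms[[2]]$azimuth + ii[2] * tw, bond[2], 360))))
    }
  }
  cands
}

#' Select the unique cross-link for one edge and repeat
#'
#' Applies the selection criteria to a candidate list: every bead must lie
#' between the two filament axes, and the rank-1 domain must sit toward the
#' pointed end of the filament relative to the rank-2 domain (for a
#' pointed-up bundle: at higher z). This polarity rule is what eliminates
#' the reciprocal, 180-degree-swapped conformation and leaves a single
#' unique cross-linking site per repeat. Remaining ties are broken
#' deterministically (lowest rank-1 monomer index, then filament index).
#'
#' @param candidates List from [enumerate_crosslink_candidates()].
#' @param spec The cross-linker [component_spec()].
#' @param between_tol Slack (A) for the between-filaments re-check.
#' @return A single candidate placement.
#' @export
select_crosslink <- function(candidates, spec, between_tol = 5) {
  if (!length(candidates))
    stop("no cross-link candidates to select from")
  ok <- vapply(candidates, function(cc) {
    between <- cc$t_range[1] >= -between_tol &&
      cc$t_range[2] <= cc$edge_length + between_tol
    d <- cc$domains[order(cc$domains$rank), ]
    between && d$z[1] > d$z[2]
  }, logical(1))
  kept <- candidates[ok]
  if (!length(kept)) {
    cc <- candidates[[1]]
    stop(sprintf(
      "placement failure for '%s' on edge (%d, %d), repeat %d: no candidate %s",
      spec$name, cc$edge[1], cc$edge[2], cc$repeat_index,
      "satisfies the between-filaments and polarity criteria"))
  }
  key <- vapply(kept, function(cc) {
    d <- cc$domains[order(cc$domains$rank), ]
    d$monomer[1] * 1e6 + d$filament[1] * 1e3 + d$monomer[2]
  }, numeric(1))
  kept[[which.min(key)]]
}

#' Place every cross-linker in the bundle
#'
#' One fimbrin and one villin per edge per complete 13-monomer repeat,
#' selected by [enumerate_crosslink_candidates()] and [select_crosslink()].
#' Partial top/bottom repeats are left bare. With the surrogate
#' specifications the two species land on distinct monomer levels of every
#' edge (vertically staggered), and placements of one direction class share
#' their level to within one monomer rise.
#'
#' @param bundle An [build_bundle()] object.
#' @param fimbrin,villin Cross-linker [component_spec()]s; `NULL` drops the
#'   species. Defaults are the surrogate specs phased to the bundle twist.
#' @param flexibility,between_tol Passed to the enumerator.
#' @return A `placement_set`.
#' @export
place_all_crosslinkers <- function(bundle,
                                   fimbrin = surrogate_spec(
                                     "fimbrin", twist = bundle$sym$twist),
                                   villin = surrogate_spec(
                                     "villin", twist = bundle$sym$twist),
                                   flexibility = NULL, between_tol = 5) {
  stopifnot(inherits(bundle, "actin_bundle"))
  if (!has_closure(bundle$sym))
    stop("bundle symmetry has no repeat closure")
  if (is.null(flexibility))
    flexibility <- hexagonal_mismatch(bundle$sym)$max_deviation
  u <- bundle$sym$units_per_repeat
  n_rep <- bundle$n_monomers %/% u
  specs <- Filter(Negate(is.null), list(fimbrin = fimbrin, villin = villin))
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  edges <- bundle$edges
  acc <- list()
  for (spec in specs) {
    inst <- 0L
    for (e in seq_len(nrow(edges))) {
      for (r in seq_len(n_rep) - 1L) {
        cands <- enumerate_crosslink_candidates(
          bundle, spec, edges[e, ], r, flexibility = flexibility,
          between_tol = between_tol)
        sel <- select_crosslink(cands, spec, between_tol = between_tol)
        inst <- inst + 1L
        d <- sel$domains
        acc[[length(acc) + 1L]] <- data.table::data.table(
          component = spec$name, instance = inst, domain = d$domain,
          rank = d$rank, filament = d$filament, monomer = d$monomer,
          class = sel$class, px = d$px, py = d$py, ang = d$ang, z0 = d$z0,
          x = d$x, y = d$y, z = d$z, dev = d$dev,
          edge_a = sel$edge[1], edge_b = sel$edge[2],
          repeat_index = sel$repeat_index)
      }
    }
  }
  rows <- if (length(acc)) data.table::rbindlist(acc)
          else data.table::data.table()
  new_placement_set(rows, specs, bundle)
}

# ---- myosin placement -----------------------------------------------------

#' Place membrane-tethering myosin motors on the outer filaments
#'
#' Motors go only on outer-ring filaments, oriented radially outward so the
#' tail can reach the membrane. Per repeat per outer filament the two
#' clash-free sites of highest radial extension are kept (extension =
#' outermost-bead reach projected on the outward radial direction, which
#' penalizes sites facing away from the membrane); one additional,
#' third-best site is placed on the outer filament at the turn's starting
#' azimuth once per 360-degree turn of the long-pitch helix (every two
#' repeats for 13/6 actin). The lever is built at the rigor orientation
#' encoded in the motor spec.
#'
#' @param bundle An [build_bundle()] object with at least one ring.
#' @param spec Motor [component_spec()]; default surrogate myosin phased to
#'   the bundle twist.
#' @param min_radial_extension Minimum accepted extension in Angstrom.
#' @param crosslinkers Optional `placement_set` whose beads (plus the
#'   filament beads) are obstacles for the clash check.
#' @param overlap_factor Soft-core overlap factor for the clash check.
#' @return A `placement_set` of motor placements; filaments where no
#'   clash-free site existed are recorded in `attr(, "skipped")` and raise a
#'   warning.
#' @export
place_myosin <- function(bundle, spec = surrogate_spec(
                           "myosin", twist = bundle$sym$twist),
                         min_radial_extension = 150,
                         crosslinkers = NULL, overlap_factor = 0.9) {
  stopifnot(inherits(bundle, "actin_bundle"))
  if (spec$role != "motor") stop("'spec' must be a motor")
  if (bundle$lattice$n_rings < 1)
    stop("bundle needs at least one ring of outer filaments")
  if (!has_closure(bundle$sym))
    stop("bundle symmetry has no repeat closure")
  u <- bundle$sym$units_per_repeat
  tw <- bundle$sym$twist; rise <- bundle$sym$rise
  n_rep <- bundle$n_monomers %/% u
  outer <- which(bundle$lattice$ring == bundle$lattice$n_rings)
  alpha <- (atan2(bundle$lattice$points[outer, 2],
                  bundle$lattice$points[outer, 1]) * 180 / pi) %% 360
  dom <- spec$domains[[1]]
  dmc <- domain_monomer_coords(dom)
  reach <- max(sqrt((dom$radius + dom$beads$ax)^2 + dom$beads$ay^2))
  obstacles <- placement_beads(bundle)
  if (!is.null(crosslinkers))
    obstacles <- rbind(obstacles, placement_beads(crosslinkers))
  obs_index <- bead_index(obstacles, overlap_factor)
  start_fil <- outer[which.min(alpha)]
  turn_rep <- 2L * (0:(max(0L, n_rep %/% 2L - 1L)))  # turn = 2 repeats (13/6)
  acc <- list(); inst <- 0L; skipped <- integer()
  motor_beads_placed <- list()
  candidate_beads <- function(f, i) {
    th <- i * tw * pi / 180
    co <- cos(th); si <- sin(th)
    p <- bundle$lattice$points[f, ]
    data.table::data.table(
      component = "myosin", instance = -1L, label = dom$beads$label,
      x = p[1] + dmc$beads[, 1] * co - dmc$beads[, 2] * si,
      y = p[2] + dmc$beads[, 1] * si + dmc$beads[, 2] * co,
      z = i * rise + dmc$beads[, 3],
      r = dom$beads$r, mass = dom$beads$mass)
  }
  add_motor <- function(f, i, devv, ext, extra) {
    inst <<- inst + 1L
    p <- bundle$lattice$points[f, ]
    th <- i * tw * pi / 180
    anch <- c(p, 0) + c(cos(th) * dmc$anchor[1] - sin(th) * dmc$anchor[2],
                        sin(th) * dmc$anchor[1] + cos(th) * dmc$anchor[2],
                        dmc$anchor[3] + i * rise)
    acc[[length(acc) + 1L]] <<- data.table::data.table(
      component = "myosin", instance = inst, domain = dom$name, rank = 1L,
      filament = f, monomer = i, class = NA_character_,
      px = p[1], py = p[2], ang = i * tw, z0 = i * rise,
      x = anch[1], y = anch[2], z = anch[3], dev = devv,
      extension = ext, extra = extra)
  }
  clash_free <- function(cb) {
    if (clash_any(cb, obs_index, overlap_factor)) return(FALSE)
    for (mb in motor_beads_placed) {
      if (min(abs(mb$z[1] - cb$z[1])) > 500) next
      dd <- outer(cb$x, mb$x, "-")^2 + outer(cb$y, mb$y, "-")^2 +
        outer(cb$z, mb$z, "-")^2
      lim <- outer(cb$r, mb$r, "+") * overlap_factor
      if (any(dd < lim^2)) return(FALSE)
    }
    TRUE
  }
  for (k in seq_along(outer)) {
    f <- outer[k]
    placed_any <- FALSE
    for (r in seq_len(n_rep) - 1L) {
      win <- (u * r):(u * r + u - 1)
      dev <- circ_dist(dom$azimuth + win * tw, alpha[k], 360)
      ext <- reach * cos(pmin(dev, 90) * pi / 180)
      ord <- order(-ext, win)
      n_keep <- 0L; rank_i <- 0L
      for (o in ord) {
        if (ext[o] < min_radial_extension) break
        rank_i <- rank_i + 1L
        take <- n_keep < 2L ||
          (rank_i == 3L && f == start_fil && r %in% turn_rep)
        if (!take) next
        cb <- candidate_beads(f, win[o])
        if (!clash_free(cb)) next
        add_motor(f, win[o], dev[o], ext[o], extra = rank_i == 3L)
        motor_beads_placed[[length(motor_beads_placed) + 1L]] <- cb
        n_keep <- n_keep + 1L
        placed_any <- TRUE
        if (rank_i >= 3L) break
      }
    }
    if (!placed_any) skipped <- c(skipped, f)
  }
  if (length(skipped))
    warning("no clash-free myosin site on filament(s): ",
            paste(skipped, collapse = ", "))
  rows <- if (length(acc)) data.table::rbindlist(acc)
          else data.table::data.table()
  out <- new_placement_set(rows, stats::setNames(list(spec), spec$name),
                           bundle)
  attr(out, "skipped") <- skipped
  out
}

#' Attach calmodulin light chains to placed motors
#'
#' One light chain per IQ attachment frame of the motor spec, poses
#' propagated rigidly with the motor: three per motor.
#'
#' @param motors A `placement_set` from [place_myosin()].
#' @param spec Light-chain [component_spec()].
#' @return A `placement_set` of light-chain placements.
#' @export
attach_light_chains <- function(motors,
                                spec = surrogate_spec("light_chain")) {
  stopifnot(inherits(motors, "placement_set"))
  m <- motors$placements
  mspec <- motors$specs[[1]]
  if (is.null(mspec$iq_frames)) stop("motor spec carries no IQ frames")
  if (!nrow(m))
    return(new_placement_set(data.table::data.table(),
                             stats::setNames(list(spec), spec$name),
                             motors$bundle))
  dom <- mspec$domains[[1]]
  thd <- dom$azimuth * pi / 180
  M <- cbind(c(cos(thd), sin(thd), 0), c(-sin(thd), cos(thd), 0), c(0, 0, 1))
  frames_m <- t(dom$radius * c(cos(thd), sin(thd), 0) +
                  M %*% t(mspec$iq_frames))  # monomer frame
  acc <- vector("list", nrow(frames_m))
  for (k in seq_len(nrow(frames_m))) {
    th <- m$ang * pi / 180
    fx <- frames_m[k, 1]; fy <- frames_m[k, 2]; fz <- frames_m[k, 3]
    wx <- m$px + fx * cos(th) - fy * sin(th)
    wy <- m$py + fx * sin(th) + fy * cos(th)
    wz <- m$z0 + fz
    acc[[k]] <- data.table::data.table(
      component = spec$name, instance = 0L,
      domain = spec$domains[[1]]$name, rank = 1L,
      filament = m$filament, monomer = m$monomer, class = NA_character_,
      px = wx, py = wy, ang = 0, z0 = wz, x = wx, y = wy, z = wz,
      dev = NA_real_, motor_instance = m$instance, iq = k)
  }
  rows <- data.table::rbindlist(acc)[order(motor_instance, iq)]
  rows[, instance := seq_len(.N)]
  out <- new_placement_set(rows, stats::setNames(list(spec), spec$name),
                           motors$bundle)
  # a light chain is bound to its motor; the contact is not a steric clash
  attr(out, "bonded") <- data.table::data.table(
    component_a = mspec$name, instance_a = rows$motor_instance,
    component_b = spec$name, instance_b = rows$instance)
  out
}

#' Barber-pole geometry of the motor decoration
#'
#' The axial register of the bundle transfers the filament twist to the
#' outer surface: motor anchors trace helical strands around the bundle.
#' This fits the strand count, pitch and handedness from the anchors alone
#' by walking the anchors filament-to-filament around the bundle (the pitch
#' is the z gained per 360 degrees of azimuth) and clustering the axial
#' offsets of all anchors about that helix. For 13/6 actin the motors form
#' a double-helical ("barber pole") pattern whose pitch is the long-pitch
#' helix repeat, 26 monomers (717 A).
#'
#' @param motors A `placement_set` from [place_myosin()].
#' @return List with `n_strands`, `pitch` (A per turn), `handedness`
#'   ("right" or "left"), and the fitted `rise_per_filament_step`.
#' @export
barber_pole_parameters <- function(motors) {
  stopifnot(inherits(motors, "placement_set"))
  m <- motors$placements
  if (!nrow(m) || length(unique(m$filament)) < 3)
    stop("too few motors to fit a barber pole (need a full turn)")
  az <- (atan2(m$py, m$px) * 180 / pi) %% 360
  sec <- sort(unique(round(az, 6)))
  ns <- length(sec)
  sector <- match(round(az, 6), sec)
  zs <- split(m$z, sector)
  if (length(zs) < ns || ns < 3) stop("motors do not cover the bundle")
  # walk a strand upward around the bundle: the pitch is the z gained per
  # full 360-degree circuit (this absorbs the once-per-turn double step)
  cur_s <- 1L; cur_z <- min(zs[[1L]])
  circuit_gain <- numeric()
  z_at_start <- cur_z; steps <- 0L
  repeat {
    nxt <- if (cur_s == ns) 1L else cur_s + 1L
    cand <- zs[[nxt]][zs[[nxt]] >= cur_z - 1e-6]
    if (!length(cand) || length(circuit_gain) >= 4L) break
    cur_z <- min(cand); cur_s <- nxt; steps <- steps + 1L
    if (cur_s == 1L) {
      circuit_gain <- c(circuit_gain, cur_z - z_at_start)
      z_at_start <- cur_z
    }
  }
  if (!length(circuit_gain))
    stop("too few motors to fit a barber pole (need a full turn)")
  pitch <- mean(circuit_gain)
  slope <- pitch / 360
  off <- sort((m$z - slope * az) %% pitch)
  gaps <- diff(c(off, off[1] + pitch))
  n_strands <- max(1L, sum(gaps > 0.2 * pitch))
  list(n_strands = as.integer(n_strands), pitch = pitch,
       handedness = if (slope >= 0) "right" else "left",
       rise_per_filament_step = pitch / ns)
}
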