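#' Helical symmetry operator
#'
#' Defines a screw symmetry by its rise (Angstrom per subunit) and twist
#' (degrees per subunit) and detects repeat closure: the smallest number of
#' subunits `u` whose accumulated twist is, within `closure_tolerance`
#' degrees, a whole number of turns `t`. F-actin in the microvillar core
#' bundle has rise 27.57 A and twist -166.154 deg, closing at 13 subunits in
#' 6 turns ("13/6 symmetry"). The slight departure from ideal 13/6 reported
#' for the isolated filament (an extra 0.25 deg/monomer) does not close
#' within 13 subunits and is represented as a symmetry without closure.
#'
#' @param rise Rise per subunit in Angstrom; must be positive.
#' @param twist Twist per subunit in degrees; normalized to (-180, 180].
#'   Negative values are left-handed (the actin genetic helix).
#' @param closure_tolerance Closure acceptance in degrees. The default 0.01
#'   accepts twists printed to typical literature precision (the exact 13/6
#'   twist is -2160/13 = -166.153846 deg; the printed -166.154 accumulates a
#'   0.002 deg residual over 13 subunits) while rejecting genuine symmetry
#'   departures such as -166.404 (closest approach 3.25 deg within 13
#'   subunits).
#' @param max_units Largest repeat length searched for closure.
#' @return An object of class `helical_symmetry`: a list with `rise`,
#'   `twist`, `units_per_repeat`, `turns_per_repeat` (both `NA` when no
#'   closure is found), and `closure_tolerance`.
#' @examples
#' actin <- make_symmetry(27.57, -166.154)
#' actin$units_per_repeat  # 13
#' actin$turns_per_repeat  # 6
#' @seealso [achievable_axes()], [hexagonal_mismatch()], [monomer_transform()]
#' @export
make_symmetry <- function(rise, twist, closure_tolerance = 0.01,
                          max_units = 1000) {
  if (!is.numeric(rise) || length(rise) != 1L || !is.finite(rise) || rise <= 0)
    stop("'rise' must be a single positive number (Angstrom)")
  if (!is.numeric(twist) || length(twist) != 1L || !is.finite(twist))
    stop("'twist' must be a single finite number (degrees)")
  if (max_units < 1) stop("'max_units' must be at least 1")
  tw <- twist %% 360
  if (tw > 180) tw <- tw - 360
  if (tw == 0) stop("zero twist: degenerate (non-helical) symmetry")
  u <- NA_integer_
  tt <- NA_integer_
  for (k in seq_len(max_units)) {
    resid <- circ_dist(k * tw, 0, 360)
    if (resid <= closure_tolerance) {
      u <- as.integer(k)
      tt <- as.integer(round(k * abs(tw) / 360))
      break
    }
  }
  structure(list(rise = rise, twist = tw, units_per_repeat = u,
                 turns_per_repeat = tt,
                 closure_tolerance = closure_tolerance),
            class = "helical_symmetry")
}

#' @export
print.helical_symmetry <- function(x, ...) {
  cat(sprintf("helical symmetry: rise %.4g A, twist %.6g deg", x$rise, x$twist))
  if (!is.na(x$units_per_repeat))
    cat(sprintf("  (%d/%d repeat)", x$units_per_repeat, x$turns_per_repeat))
  else
    cat("  (no closure detected)")
  cat("\n")
  invisible(x)
}

has_closure <- function(sym) {
  inherits(sym, "helical_symmetry") && !is.na(sym$units_per_repeat)
}

#' Transform generating the i-th subunit of a helix
#'
#' The screw operator applied `i` times: rotation about z by `i * twist` and
#' translation along z by `i * rise`. Negative `i` walks the helix the other
#' way. Same-axis screw motions commute, so
#' `monomer_transform(sym, i + j) == rt_compose(monomer_transform(sym, i),
#' monomer_transform(sym, j))`.
#'
#' @param sym A [make_symmetry()] object.
#' @param i Integer subunit index (0 is the reference subunit).
#' @return A [rigid_transform()].
#' @export
monomer_transform <- function(sym, i) {
  stopifnot(inherits(sym, "helical_symmetry"))
  if (length(i) != 1L || i != round(i)) stop("'i' must be a single integer")
  rigid_transform(rot_z(i * sym$twist), c(0, 0, i * sym$rise))
}

#' Achievable cross-link axis orientations of a closed helix
#'
#' In an axially registered bundle every filament presents the same set of
#' azimuthal site orientations, one per subunit of the repeat:
#' `k * twist` for `k = 0 .. units_per_repeat - 1`. Cross-link axes are
#' undirected, so orientations are reduced modulo 180 degrees and
#' deduplicated. For 13/6 actin this is 13 axes uniformly spaced
#' 180/13 = 13.85 degrees apart; for an ideal hexagonal (6/1) helix it is
#' {0, 60, 120}.
#'
#' @param sym A closed [make_symmetry()] object.
#' @param dedup_tolerance Angular deduplication tolerance in degrees.
#' @return Sorted numeric vector of axis angles in `[0, 180)` degrees.
#' @export
achievable_axes <- function(sym, dedup_tolerance = 1e-6) {
  stopifnot(inherits(sym, "helical_symmetry"))
  if (!has_closure(sym))
    stop("symmetry has no detected closure; achievable axes are undefined")
  k <- seq_len(sym$units_per_repeat) - 1
  ax <- sort((k * sym$twist) %% 180)
  keep <- c(TRUE, diff(ax) > dedup_tolerance)
  # first and last can alias across the 0/180 wrap
  if (sum(keep) > 1 && (180 - ax[length(ax)] + ax[1]) <= dedup_tolerance)
    keep[length(keep)] <- FALSE
  ax[keep]
}

#' Hexagonal-lattice mismatch of a helical filament
#'
#' Quantifies how well a helix with the given symmetry can serve the three
#' bond directions (0, 60, 120 degrees) of a hexagonal filament lattice.
#'
#' `max_deviation` is the worst-case angular accommodation a cross-linker
#' must supply: the azimuthal phase between the actin-binding site
#' orientation and the lattice bond axes is fixed by the binding chemistry
#' and is not tunable, so the bound is taken over every possible phase. It
#' equals half the widest gap between adjacent achievable axes; for 13/6
#' actin this is 6.92 degrees (the "+-7 degrees" of flexibility a
#' microvillar cross-linker must have). `class_deviation` reports the
#' per-direction deviations at zero phase (0, 4.62, 4.62 degrees for 13/6).
#'
#' `uniqueness_spacing` is the smallest gap between distinct achievable
#' axes: a cross-linker more flexible than this could bind two neighbouring
#' orientations (in particular, the genuine conformation and its 180-degree
#' reciprocal) and the bundle would lose its single unique cross-linking
#' site per repeat. For 13/6 actin this is 13.85 degrees (the "< +-14
#' degrees" bound).
#'
#' @param sym A closed [make_symmetry()] object.
#' @return A list with `max_deviation`, `uniqueness_spacing` (both degrees)
#'   and `class_deviation` (named vector for the d/e/f bond directions at
#'   0/60/120 degrees).
#' @examples
#' hexagonal_mismatch(make_symmetry(27.57, -166.154))
#' @export
hexagonal_mismatch <- function(sym) {
  ax <- achievable_axes(sym)
  gaps <- if (length(ax) > 1) diff(c(ax, ax[1] + 180)) else 180
  cls <- vapply(c(d = 0, e = 60, f = 120),
                function(b) min(circ_dist(b, ax, 180)), numeric(1))
  list(max_deviation = max(gaps) / 2,
       uniqueness_spacing = min(gaps),
       class_deviation = cls)
}
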