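# cell-list index over a bead table; cell edge = largest possible contact
# distance so every potentially clashing pair shares adjacent cells
bead_index <- function(beads, overlap_factor = 0.9) {
  beads <- data.table::as.data.table(beads)
  cell <- max(2 * max(beads$r) * overlap_factor, 1e-6)
  dt <- data.table::copy(beads)
  dt[, `:=`(cx = as.integer(floor(x / cell)),
            cy = as.integer(floor(y / cell)),
            cz = as.integer(floor(z / cell)))]
  data.table::setkey(dt, cx, cy, cz)
  structure(list(dt = dt, cell = cell), class = "bead_index")
}

# TRUE if any bead in 'beads' overlaps any indexed bead
clash_any <- function(beads, index, overlap_factor = 0.9) {
  dt <- index$dt; cell <- index$cell
  reach <- overlap_factor * (max(beads$r) + max(dt$r))
  nr <- max(1L, as.integer(ceiling(reach / cell)))
  offs <- as.matrix(expand.grid(dx = -nr:nr, dy = -nr:nr, dz = -nr:nr))
  nb <- nrow(beads)
  q <- data.table::data.table(
    cx = rep(as.integer(floor(beads$x / cell)), nrow(offs)) +
      rep(offs[, 1], each = nb),
    cy = rep(as.integer(floor(beads$y / cell)), nrow(offs)) +
      rep(offs[, 2], each = nb),
    cz = rep(as.integer(floor(beads$z / cell)), nrow(offs)) +
      rep(offs[, 3], each = nb),
    qx = rep(beads$x, nrow(offs)), qy = rep(beads$y, nrow(offs)),
    qz = rep(beads$z, nrow(offs)), qr = rep(beads$r, nrow(offs)))
  hit <- dt[q, on = c("cx", "cy", "cz"), nomatch = 0L,
            allow.cartesian = TRUE]
  nrow(hit) > 0 &&
    any((hit$x - hit$qx)^2 + (hit$y - hit$qy)^2 + (hit$z - hit$qz)^2 <
          (overlap_factor * (hit$r + hit$qr))^2)
}

#' Detect steric clashes between placed components
#'
#' Reports every pair of beads from distinct component instances whose
#' center distance is below `overlap_factor` times the sum of their radii.
#' A soft-core factor below 1 (default 0.9) compensates for coarse beads
#' overestimating molecular envelopes. The search uses a spatial-hash cell
#' list; the result is sorted and therefore independent of input order, and
#' agrees exactly with an all-pairs scan.
#'
#' @param x A bead table (see [placement_beads()]), a `placement_set`, or a
#'   list of either to be combined.
#' @param overlap_factor Soft-core overlap factor.
#' @param bonded Optional data.table of covalently/stoichiometrically bound
#'   instance pairs to exempt (columns `component_a`, `instance_a`,
#'   `component_b`, `instance_b`), e.g. a motor and its own light chains.
#'   Bonded-pair tables attached to placement sets (as produced by
#'   [attach_light_chains()]) are collected automatically.
#' @return data.table with one row per clashing pair: components,
#'   instances, labels, centers distance `dist` and contact limit `limit`.
#' @examples
#' b <- data.frame(component = c("a", "b"), instance = 1L,
#'                 label = "X", x = 0, y = 0, z = c(0, 1), r = 5, mass = 1)
#' nrow(detect_clashes(b))
#' @export
detect_clashes <- function(x, overlap_factor = 0.9, bonded = NULL) {
  bonded <- data.table::rbindlist(c(list(bonded), collect_bonded(x)),
                                  fill = TRUE)
  beads <- as_bead_table(x)
  n <- nrow(beads)
  empty <- data.table::data.table(
    component_a = character(), instance_a = integer(), label_a = character(),
    component_b = character(), instance_b = integer(), label_b = character(),
    dist = numeric(), limit = numeric())
  if (n < 2) return(empty)
  cell <- max(2 * max(beads$r) * overlap_factor, 1e-6)
  dt <- data.table::data.table(
    idx = seq_len(n), comp = beads$component, inst = beads$instance,
    lab = beads$label, x = beads$x, y = beads$y, z = beads$z, r = beads$r,
    cx = as.integer(floor(beads$x / cell)),
    cy = as.integer(floor(beads$y / cell)),
    cz = as.integer(floor(beads$z / cell)))
  data.table::setkey(dt, cx, cy, cz)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  found <- list()
  for (k in seq_len(nrow(offs))) {
    q <- data.table::data.table(
      cx = dt$cx + offs[k, 1], cy = dt$cy + offs[k, 2],
      cz = dt$cz + offs[k, 3],
      qidx = dt$idx, qcomp = dt$comp, qinst = dt$inst, qlab = dt$lab,
      qx = dt$x, qy = dt$y, qz = dt$z, qr = dt$r)
    hit <- dt[q, on = c("cx", "cy", "cz"), nomatch = 0L,
              allow.cartesian = TRUE]
    hit <- hit[idx < qidx & !(comp == qcomp & inst == qinst)]
    if (!nrow(hit)) next
    hit[, `:=`(dist = sqrt((x - qx)^2 + (y - qy)^2 + (z - qz)^2),
               limit = overlap_factor * (r + qr))]
    hit <- hit[dist < limit]
    if (nrow(hit)) found[[length(found) + 1L]] <- hit
  }
  if (!length(found)) return(empty)
  res <- unique(data.table::rbindlist(found), by = c("idx", "qidx"))
  out <- res[, .(component_a = comp, instance_a = inst, label_a = lab,
                 component_b = qcomp, instance_b = qinst, label_b = qlab,
                 dist = dist, limit = limit)]
  if (nrow(bonded)) {
    bkey <- c(paste(bonded$component_a, bonded$instance_a,
                    bonded$component_b, bonded$instance_b),
              paste(bonded$component_b, bonded$instance_b,
                    bonded$component_a, bonded$instance_a))
    out <- out[!(paste(component_a, instance_a, component_b, instance_b)
                 %in% bkey)]
  }
  out[order(component_a, instance_a, label_a, component_b, instance_b,
            label_b)]
}

collect_bonded <- function(x) {
  if (inherits(x, "placement_set")) {
    b <- attr(x, "bonded")
    return(if (is.null(b)) list() else list(b))
  }
  if (is.list(x) && !is.data.frame(x))
    return(unlist(lapply(x, collect_bonded), recursive = FALSE))
  list()
}

as_bead_table <- function(x) {
  if (inherits(x, "placement_set")) return(placement_beads(x))
  if (inherits(x, "actin_bundle")) return(bundle_beads(x))
  if (is.data.frame(x)) {
    need <- c("component", "instance", "label", "x", "y", "z", "r")
    if (!all(need %in% names(x)))
      stop("bead table needs columns: ", paste(need, collapse = ", "))
    return(data.table::as.data.table(x))
  }
  if (is.list(x))
    return(data.table::rbindlist(lapply(x, as_bead_table), fill = TRUE))
  stop("cannot interpret 'x' as beads")
}
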