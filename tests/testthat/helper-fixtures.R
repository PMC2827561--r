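# shared fixtures, built in code; cached per session for speed

actin_sym <- function() make_symmetry(27.57, -166.154)

# bundle with a given number of complete 13-monomer repeats
repeat_bundle <- local({
  cache <- list()
  function(rings = 2, repeats = 3) {
    key <- paste(rings, repeats)
    if (is.null(cache[[key]]))
      cache[[key]] <<- build_bundle(actin_sym(), hex_points(rings, 120),
                                    repeats * 13 * 2.757 + 0.1)
    cache[[key]]
  }
})

small_crosslinkers <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- place_all_crosslinkers(repeat_bundle())
    cache
  }
})

# O(n^2) all-pairs clash oracle over a bead table
brute_force_clashes <- function(beads, overlap_factor = 0.9) {
  n <- nrow(beads)
  out <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (beads$component[i] == beads$component[j] &&
        beads$instance[i] == beads$instance[j]) next
    d <- sqrt((beads$x[i] - beads$x[j])^2 + (beads$y[i] - beads$y[j])^2 +
                (beads$z[i] - beads$z[j])^2)
    lim <- overlap_factor * (beads$r[i] + beads$r[j])
    if (d < lim)
      out[[length(out) + 1L]] <- data.frame(
        component_a = beads$component[i], instance_a = beads$instance[i],
        label_a = beads$label[i],
        component_b = beads$component[j], instance_b = beads$instance[j],
        label_b = beads$label[j], dist = d, limit = lim)
  }
  if (!length(out))
    return(data.frame(component_a = character(), instance_a = integer(),
                      label_a = character(), component_b = character(),
                      instance_b = integer(), label_b = character(),
                      dist = numeric(), limit = numeric()))
  do.call(rbind, out)
}

# canonical unordered-pair key for comparing clash tables
pair_key <- function(cl) {
  k1 <- paste(cl$component_a, cl$instance_a, cl$label_a)
  k2 <- paste(cl$component_b, cl$instance_b, cl$label_b)
  sort(paste(pmin(k1, k2), pmax(k1, k2)))
}

rotation_angle_deg <- function(R) {
  acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}
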