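#' Binding domain of a multi-domain component
#'
#' One rigid domain of a cross-linker or motor, described relative to the
#' actin monomer it binds (the "monomer frame": origin on the filament axis
#' at the monomer's z, +x toward the monomer's azimuthal reference
#' direction). The domain sits at `radius` Angstrom from the filament axis
#' along its `azimuth` (the direction the binding surface faces) and carries
#' a coarse bead footprint given in the domain frame: x along the facing
#' direction, y perpendicular (right-handed), z along the filament axis.
#'
#' @param name Domain name (e.g. "ABD1", "headpiece", "motor").
#' @param polarity_rank Integer; rank 1 sits nearest the pointed (minus)
#'   end. Fimbrin's ABD1 and villin's V1-6 are rank 1.
#' @param azimuth Facing azimuth in the monomer frame, degrees.
#' @param radius Distance of the domain anchor from the filament axis, A.
#' @param z_offset Axial offset of the anchor from the monomer z, A.
#' @param beads data.frame with columns `label`, `ax`, `ay`, `az` (domain
#'   frame offsets from the anchor, A), `r` (bead radius, A), `mass` (Da).
#' @param attach Domain-frame point (length 3) used when measuring the
#'   linker separation between the two domains of a cross-linker.
#' @return Object of class `binding_domain`.
#' @export
binding_domain <- function(name, polarity_rank, azimuth, radius,
                           z_offset = 0, beads, attach = c(0, 0, 0)) {
  beads <- as.data.frame(beads)
  need <- c("label", "ax", "ay", "az", "r", "mass")
  if (!all(need %in% names(beads)))
    stop("'beads' needs columns: ", paste(need, collapse = ", "))
  if (any(beads$r <= 0)) stop("bead radii must be positive")
  if (any(beads$mass < 0)) stop("bead masses must be non-negative")
  structure(list(name = as.character(name),
                 polarity_rank = as.integer(polarity_rank),
                 azimuth = as.numeric(azimuth),
                 radius = as.numeric(radius),
                 z_offset = as.numeric(z_offset),
                 beads = beads,
                 attach = as.numeric(attach)),
            class = "binding_domain")
}

#' Component specification
#'
#' A parameterized multi-domain protein: a cross-linker (exactly two
#' actin-binding domains joined by a linker with a maximum separation), a
#' motor (one actin-binding domain plus a neck carrying light-chain
#' attachment frames), or a light chain. These specifications, not atomic
#' coordinates, drive placement; [surrogate_spec()] provides the default
#' parameterization for the microvillar components.
#'
#' @param name Component name.
#' @param role One of "crosslinker", "motor", "light_chain", "filament".
#' @param domains List of [binding_domain()] objects.
#' @param linker_max For cross-linkers: maximum separation (A) between the
#'   two domains' attach points.
#' @param iq_frames For motors: matrix (one row per light chain) of
#'   domain-frame attachment positions along the neck.
#' @param notes Free-text provenance notes.
#' @return Object of class `component_spec`.
#' @export
component_spec <- function(name, role, domains, linker_max = NULL,
                           iq_frames = NULL, notes = NULL) {
  role <- match.arg(role, c("crosslinker", "motor", "light_chain",
                            "filament"))
  if (!length(domains) || !all(vapply(domains, inherits, logical(1),
                                      "binding_domain")))
    stop("'domains' must be a non-empty list of binding_domain objects")
  names(domains) <- vapply(domains, `[[`, character(1), "name")
  x <- structure(list(name = as.character(name), role = role,
                      domains = domains,
                      linker_max = if (!is.null(linker_max))
                        as.numeric(linker_max),
                      iq_frames = if (!is.null(iq_frames))
                        as.matrix(iq_frames),
                      notes = notes),
                 class = "component_spec")
  validate_component_spec(x)
  x
}

#' @rdname component_spec
#' @param x Object to validate.
#' @export
validate_component_spec <- function(x) {
  stopifnot(inherits(x, "component_spec"))
  if (x$role == "crosslinker") {
    if (length(x$domains) != 2L)
      stop("cross-linker '", x$name, "' must have exactly 2 actin-binding ",
           "domains")
    rk <- vapply(x$domains, `[[`, integer(1), "polarity_rank")
    if (anyDuplicated(rk))
      stop("cross-linker domains must have distinct polarity ranks")
    if (is.null(x$linker_max) || x$linker_max < 0)
      stop("cross-linker '", x$name, "' needs a non-negative 'linker_max'")
  }
  if (x$role == "motor") {
    if (length(x$domains) != 1L)
      stop("motor '", x$name, "' must have exactly 1 actin-binding domain")
    if (is.null(x$iq_frames) || nrow(x$iq_frames) != 3L ||
        ncol(x$iq_frames) != 3L)
      stop("motor '", x$name, "' needs a 3 x 3 'iq_frames' matrix ",
           "(three light-chain attachment frames)")
  }
  invisible(x)
}

#' @export
print.component_spec <- function(x, ...) {
  cat(sprintf("component spec '%s' (%s): %d domain(s)\n", x$name, x$role,
              length(x$domains)))
  for (d in x$domains)
    cat(sprintf("  %s: rank %d, azimuth %.3f deg, radius %.1f A, %d bead(s)\n",
                d$name, d$polarity_rank, d$azimuth, d$radius, nrow(d$beads)))
  if (!is.null(x$linker_max))
    cat(sprintf("  linker max separation: %.1f A\n", x$linker_max))
  invisible(x)
}

# domain-frame -> monomer-frame coordinates of the beads (and attach point)
domain_monomer_coords <- function(dom) {
  th <- dom$azimuth * pi / 180
  xh <- c(cos(th), sin(th), 0)
  yh <- c(-sin(th), cos(th), 0)
  zh <- c(0, 0, 1)
  anchor <- dom$radius * xh + c(0, 0, dom$z_offset)
  M <- cbind(xh, yh, zh)
  beads <- t(anchor + M %*% t(as.matrix(dom$beads[, c("ax", "ay", "az")])))
  attach <- anchor + as.numeric(M %*% dom$attach)
  list(anchor = anchor, beads = beads, attach = attach)
}

# per-monomer azimuthal step of the site lattice as seen mod 360 (two
# genetic monomers advance one long-pitch step of 360 + 2*twist)
long_pitch_step <- function(sym) (360 + 2 * sym$twist) %% 360

#' Default surrogate component parameterizations
#'
#' Coarse-grained, parameterized stand-ins for the microvillar components.
#' The EM-fitted cross-link coordinates the bundle model was originally
#' built from are not deposited, so these surrogates encode only the
#' documented topology and placement-relevant geometry; all numbers are
#' tunable through [component_spec()] / spec files.
#'
#' \describe{
#' \item{fimbrin}{Compact two-ABD cross-linker: two 15 A ABD beads 40 A off
#'   their filament axes plus a two-bead core, bridging the 120 A
#'   inter-filament gap. ABD2 binds one monomer below ABD1, so ABD1 sits
#'   toward the pointed end (the polarity selection rule).}
#' \item{villin}{Six-bead V1-6 arc (rank 1, toward the pointed end) plus a
#'   single headpiece bead one monomer below, joined by an unstructured
#'   linker constrained to 40 A between V6 and the headpiece.}
#' \item{myosin}{Single motor-domain bead at the filament surface plus a
#'   three-segment neck rising at the rigor lever angle (default 80 degrees
#'   to the filament axis) to a tail anchor 175 A out - enough radial reach
#'   to span from the core bundle surface to the membrane. Three IQ frames
#'   along the neck accept calmodulin light chains.}
#' \item{light_chain}{A single calmodulin bead.}
#' \item{actin}{One 25 A monomer bead per site.}
#' \item{spectrin_repeat}{One 10 A bead per repeat for coarse terminal-web
#'   paths.}
#' }
#'
#' The cross-linker binding azimuths are phased so that each direction
#' class of the hexagonal lattice is served by one unique monomer per
#' 13-monomer repeat (fimbrin ABD1 levels 1/5/9 for classes d/e/f, villin
#' V1-6 levels 10/1/5), which staggers the two species vertically on every
#' edge.
#'
#' @param component One of "actin", "fimbrin", "villin", "myosin",
#'   "light_chain", "spectrin_repeat".
#' @param lever_angle Motor lever (neck) angle to the filament axis,
#'   degrees; default 80 (the near-perpendicular rigor orientation).
#' @param twist Filament twist used to phase the binding azimuths, degrees.
#' @return A [component_spec()].
#' @export
surrogate_spec <- function(component = c("actin", "fimbrin", "villin",
                                         "myosin", "light_chain",
                                         "spectrin_repeat"),
                           lever_angle = 80, twist = -166.154) {
  component <- match.arg(component)
  step <- (360 + 2 * twist) %% 360            # 27.69 deg for actin
  phi1 <- (-twist + step / 6) %% 360          # fimbrin ABD1 facing phase
  bead <- function(label, ax, ay, az, r, mass)
    data.frame(label = label, ax = ax, ay = ay, az = az, r = r, mass = mass)
  switch(component,
    actin = component_spec(
      "actin", "filament",
      list(binding_domain("monomer", 1L, 0, 0,
                          beads = bead("ACT", 0, 0, 0, 25, 41800)))),
    fimbrin = component_spec(
      "fimbrin", "crosslinker",
      list(binding_domain("ABD1", 1L, phi1, 40,
                          beads = rbind(
                            bead("AB1", 0, 0, 0, 15, 20000),
                            bead("CO1", 13, 0, -9, 12, 15000),
                            bead("CO2", 27, 0, -18, 12, 15000))),
           binding_domain("ABD2", 2L, (phi1 + 180 + twist) %% 360, 40,
                          beads = bead("AB2", 0, 0, 0, 15, 20000))),
      linker_max = 55),
    villin = component_spec(
      "villin", "crosslinker",
      list(binding_domain("V1-6", 1L, (phi1 + 2 * step) %% 360, 40,
                          beads = rbind(
                            bead("V1", 0, 0, 9, 9, 13000),
                            bead("V2", 2, 0, 0, 9, 13000),
                            bead("V3", 5, 0, -7, 9, 13000),
                            bead("V4", 9, 0, -13, 9, 13000),
                            bead("V5", 13, 0, -17, 9, 13000),
                            bead("V6", 15, 0, -20, 9, 13000)),
                          attach = c(15, 0, -20)),
           binding_domain("headpiece", 2L,
                          (phi1 + 2 * step + 180 + twist) %% 360, 40,
                          beads = bead("HP", 0, 0, 0, 8, 14500))),
      linker_max = 40),
    myosin = {
      sl <- tan((90 - lever_angle) * pi / 180)  # z per radial A of neck
      component_spec(
        "myosin", "motor",
        list(binding_domain("motor", 1L, 0, 50,
                            beads = rbind(
                              bead("MOT", 0, 0, 0, 25, 80000),
                              bead("NK1", 30, 0, 30 * sl, 8, 4000),
                              bead("NK2", 60, 0, 60 * sl, 8, 4000),
                              bead("NK3", 90, 0, 90 * sl, 8, 4000),
                              bead("TH1", 125, 0, 125 * sl, 12, 18000)))),
        iq_frames = cbind(c(30, 60, 90), 0, c(30, 60, 90) * sl))
    },
    light_chain = component_spec(
      "calmodulin", "light_chain",
      list(binding_domain("CaM", 1L, 0, 0,
                          beads = bead("CAM", 0, 0, 0, 12, 16700)))),
    spectrin_repeat = component_spec(
      "spectrin_repeat", "filament",
      list(binding_domain("repeat", 1L, 0, 0,
                          beads = bead("SPC", 0, 0, 0, 10, 12000)))))
}

spec_to_list <- function(x) {
  list(name = x$name, role = x$role,
       linker_max = x$linker_max,
       iq_frames = if (!is.null(x$iq_frames))
         lapply(seq_len(nrow(x$iq_frames)),
                function(i) as.numeric(x$iq_frames[i, ])),
       domains = lapply(unname(x$domains), function(d)
         list(name = d$name, polarity_rank = d$polarity_rank,
              azimuth = d$azimuth, radius = d$radius,
              z_offset = d$z_offset, attach = as.numeric(d$attach),
              beads = lapply(seq_len(nrow(d$beads)), function(i)
                as.list(d$beads[i, ])))))
}

spec_from_list <- function(l) {
  doms <- lapply(l$domains, function(d) {
    beads <- do.call(rbind, lapply(d$beads, function(b)
      data.frame(label = b$label, ax = b$ax, ay = b$ay, az = b$az,
                 r = b$r, mass = b$mass)))
    binding_domain(d$name, d$polarity_rank, d$azimuth, d$radius,
                   z_offset = if (is.null(d$z_offset)) 0 else d$z_offset,
                   beads = beads,
                   attach = if (is.null(d$attach)) c(0, 0, 0)
                            else as.numeric(d$attach))
  })
  iq <- if (!is.null(l$iq_frames) && length(l$iq_frames))
    do.call(rbind, lapply(l$iq_frames, as.numeric))
  component_spec(l$name, l$role, doms, linker_max = l$linker_max,
                 iq_frames = iq, notes = l$notes)
}

#' Read / write component specifications
#'
#' Component specifications are exchanged as structured text (YAML or JSON,
#' chosen by file extension) and validated on read.
#'
#' @param path File path; extension `.yml`/`.yaml` or `.json`.
#' @param spec A [component_spec()].
#' @return `read_component_spec` returns a validated [component_spec()];
#'   `write_component_spec` returns `path` invisibly.
#' @export
read_component_spec <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  l <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  spec_from_list(l)
}

#' @rdname read_component_spec
#' @export
write_component_spec <- function(spec, path) {
  validate_component_spec(spec)
  l <- spec_to_list(spec)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(l, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  else yaml::write_yaml(l, path)
  invisible(path)
}
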