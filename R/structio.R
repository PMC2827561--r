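#' Read an atomic structure (PDB or mmCIF)
#'
#' Thin validating wrapper around bio3d's PDB/mmCIF readers, returning a
#' plain atom table. The format is auto-detected from the extension
#' (`.pdb` / `.ent` vs `.cif` / `.mmcif`) and can be overridden. Malformed
#' or truncated files raise a parse error with record context instead of a
#' silent partial read.
#'
#' @param path File path.
#' @param format `"auto"`, `"pdb"` or `"cif"`.
#' @return Object of class `structure_model`: list with `atoms` (data.frame
#'   with `record`, `name`, `resid`, `chain`, `resno`, `x`, `y`, `z`, `o`,
#'   `b`, `elesy`) and `source`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "cif" else "pdb"
  if (format == "pdb") {
    lines <- readLines(path, warn = FALSE)
    rec <- grep("^(ATOM  |HETATM)", lines)
    if (!length(rec))
      stop("parse error in '", path, "': no ATOM/HETATM records found")
    bad <- rec[nchar(lines[rec]) < 54]
    if (length(bad))
      stop("parse error in '", path, "': truncated ATOM record at line ",
           bad[1], ": '", lines[bad[1]], "'")
    pdb <- tryCatch(
      {
        log <- utils::capture.output(
          out <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)))
        out
      },
      error = function(e)
        stop("parse error in '", path, "': ", conditionMessage(e)))
    at <- pdb$atom
  } else {
    lines <- readLines(path, warn = FALSE)
    if (!any(grepl("^_atom_site\\.", lines)))
      stop("parse error in '", path, "': no _atom_site loop found")
    pdb <- tryCatch(
      {
        log <- utils::capture.output(
          out <- suppressWarnings(bio3d::read.cif(path, verbose = FALSE)))
        out
      },
      error = function(e)
        stop("parse error in '", path, "': ", conditionMessage(e)))
    at <- pdb$atom
  }
  atoms <- data.frame(record = at$type, name = at$elety, resid = at$resid,
                      chain = at$chain, resno = at$resno,
                      x = at$x, y = at$y, z = at$z,
                      o = at$o, b = at$b, elesy = at$elesy,
                      stringsAsFactors = FALSE)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("parse error in '", path, "': non-finite coordinates")
  structure(list(atoms = atoms, source = path), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure: %d atoms, %d chain(s)\n", nrow(x$atoms),
              length(unique(x$atoms$chain))))
  invisible(x)
}

# one atom row per bead; bead radius is stored in the B-factor column so the
# coarse model round-trips through standard formats
beads_to_atoms <- function(beads, chain_prefix = NULL) {
  comp_prefix <- c(actin = "A", fimbrin = "F", villin = "V", myosin = "M",
                   calmodulin = "C", spectrin = "S")
  pref <- comp_prefix[beads$component]
  pref[is.na(pref)] <- toupper(substr(beads$component[is.na(pref)], 1, 1))
  chain <- paste0(pref, beads$instance)
  data.frame(record = "HETATM", name = substr(beads$label, 1, 4),
             resid = "BEA", chain = chain,
             resno = as.integer(beads$instance),
             x = beads$x, y = beads$y, z = beads$z,
             o = 1, b = beads$r, elesy = "C", stringsAsFactors = FALSE)
}

#' Write an assembly to PDB or mmCIF
#'
#' Writes a placed model (a `placement_set`, `actin_bundle`, bead table, a
#' list of those, or a `structure_model`) with one chain per component
#' instance, named deterministically as component prefix plus running index
#' (A1.. for filaments, F1.. fimbrin, V1.. villin, M1.. myosin, C1..
#' calmodulin). mmCIF is the default since assemblies routinely exceed the
#' PDB chain namespace; strict PDB mode refuses more than 62 chains and
#' advises mmCIF. Coordinates are written in Angstrom at format precision
#' (3 decimals). A `barbed_up` bundle polarity flips the model about the x
#' axis on output.
#'
#' @param model The model to write (must be non-empty).
#' @param path Output path.
#' @param format `"cif"` or `"pdb"`.
#' @return `path`, invisibly.
#' @export
write_assembly <- function(model, path, format = c("cif", "pdb")) {
  format <- match.arg(format)
  if (inherits(model, "structure_model")) {
    atoms <- model$atoms
  } else {
    beads <- as_bead_table(model)
    if (!nrow(beads)) stop("empty model: nothing to write")
    pol <- model_polarity(model)
    if (identical(pol, "barbed_up")) {
      beads$y <- -beads$y
      beads$z <- -beads$z
    }
    atoms <- beads_to_atoms(beads)
  }
  if (!nrow(atoms)) stop("empty model: nothing to write")
  chains <- unique(atoms$chain)
  if (format == "pdb") {
    if (length(chains) > 62)
      stop("strict PDB supports at most 62 chains (got ", length(chains),
           "); write mmCIF instead (format = 'cif')")
    chmap <- stats::setNames(
      c(LETTERS, letters, as.character(0:9))[seq_along(chains)], chains)
    bio3d::write.pdb(
      file = path, type = atoms$record, resno = atoms$resno,
      resid = atoms$resid, chain = unname(chmap[atoms$chain]),
      eleno = seq_len(nrow(atoms)), elety = atoms$name,
      xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
      o = atoms$o, b = atoms$b, elesy = atoms$elesy)
  } else {
    hdr <- c("data_assembly", "#", "loop_",
             paste0("_atom_site.",
                    c("group_PDB", "id", "type_symbol", "label_atom_id",
                      "label_comp_id", "label_asym_id", "label_entity_id",
                      "label_seq_id", "Cartn_x", "Cartn_y", "Cartn_z",
                      "occupancy", "B_iso_or_equiv", "auth_seq_id",
                      "auth_comp_id", "auth_asym_id", "auth_atom_id",
                      "pdbx_PDB_model_num")))
    n <- nrow(atoms)
    body <- sprintf(
      "%-6s %d %s %s %s %s 1 %d %.3f %.3f %.3f %.2f %.2f %d %s %s %s 1",
      atoms$record, seq_len(n), atoms$elesy, atoms$name, atoms$resid,
      atoms$chain, atoms$resno, atoms$x, atoms$y, atoms$z, atoms$o,
      atoms$b, atoms$resno, atoms$resid, atoms$chain, atoms$name)
    writeLines(c(hdr, body, "#"), path)
  }
  invisible(path)
}

model_polarity <- function(model) {
  if (inherits(model, "placement_set")) return(model$bundle$polarity)
  if (inherits(model, "actin_bundle")) return(model$polarity)
  if (is.list(model) && !is.data.frame(model))
    for (el in model) {
      p <- model_polarity(el)
      if (!identical(p, "pointed_up")) return(p)
    }
  "pointed_up"
}

#' Least-squares superposition of paired point sets
#'
#' Optimal proper rigid-body superposition (Kabsch algorithm via singular
#' value decomposition) of a mobile point set onto an equally sized,
#' correspondingly ordered reference set. Reflections are never returned.
#'
#' @param mobile,reference n x 3 coordinate matrices, n >= 3, not
#'   collinear.
#' @return List with `transform` (a [rigid_transform()] mapping mobile onto
#'   reference) and `rmsd` (A, after transformation).
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (ncol(mobile) != 3 || ncol(reference) != 3)
    stop("point sets must be n x 3 matrices")
  n <- nrow(mobile)
  if (n != nrow(reference)) stop("point sets must be paired (equal length)")
  if (n < 3) stop("degenerate alignment: need at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  sv_chk <- svd(rbind(P, Q))$d
  if (sv_chk[2] < 1e-8 * max(sv_chk[1], 1))
    stop("degenerate alignment: points are collinear")
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tvec <- cr - as.numeric(R %*% cm)
  moved <- sweep(mobile %*% t(R), 2, -tvec)
  rmsd <- sqrt(mean(rowSums((moved - reference)^2)))
  list(transform = rigid_transform(R, tvec), rmsd = rmsd)
}

#' Generate a synthetic component fixture
#'
#' Deterministic pseudo-atomic stand-in for a component: the EM-fitted
#' cross-link coordinates the microvillar model was built from are not
#' publicly deposited, so tests and the default pipeline use these
#' synthetic structures, which encode only the documented topology (e.g.
#' villin: six-repeat arc + linker + headpiece; myosin: motor + three-IQ
#' neck + tail). The same `(component, seed)` always yields byte-identical
#' output; atoms are scattered inside the component's bead envelope.
#'
#' @param component One of the [surrogate_spec()] names.
#' @param seed Integer seed (default 0).
#' @param atoms_per_bead Pseudo-atoms generated inside each bead.
#' @return List with `structure` (a `structure_model`), `beads` (bead
#'   table at the reference pose) and `spec` (the [component_spec()]).
#' @export
make_fixture <- function(component, seed = 0, atoms_per_bead = 8) {
  spec <- surrogate_spec(component)   # errors on unknown component
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(as.integer(seed))
  beads_l <- list()
  atoms_l <- list()
  for (dom in spec$domains) {
    dmc <- domain_monomer_coords(dom)
    bd <- dom$beads
    beads_l[[length(beads_l) + 1L]] <- data.table::data.table(
      component = spec$name, instance = 1L, label = bd$label,
      x = dmc$beads[, 1], y = dmc$beads[, 2], z = dmc$beads[, 3],
      r = bd$r, mass = bd$mass)
    for (k in seq_len(nrow(bd))) {
      u <- matrix(stats::runif(3 * atoms_per_bead, -1, 1), ncol = 3)
      u <- u / pmax(sqrt(rowSums(u^2)), 1e-9) *
        (bd$r[k] * 0.8 * stats::runif(atoms_per_bead)^(1 / 3))
      atoms_l[[length(atoms_l) + 1L]] <- data.frame(
        record = "ATOM", name = "CA", resid = "ALA", chain = "A",
        resno = 0L,
        x = dmc$beads[k, 1] + u[, 1], y = dmc$beads[k, 2] + u[, 2],
        z = dmc$beads[k, 3] + u[, 3], o = 1, b = 0, elesy = "C",
        stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, atoms_l)
  atoms$resno <- seq_len(nrow(atoms))
  list(structure = structure(list(atoms = atoms,
                                  source = sprintf("synthetic:%s:%d",
                                                   component, seed)),
                             class = "structure_model"),
       beads = data.table::rbindlist(beads_l),
       spec = spec)
}
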