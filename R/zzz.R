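#' paracryst: paracrystalline actin bundle models
#'
#' Builders and analytics for paracrystalline actin bundles such as the
#' microvillar core bundle: helical symmetry operators, hexagonal lattice
#' assembly, symmetry-propagated placement of cross-linkers and motors,
#' coarse-grained steric validation, stoichiometry/packing analytics,
#' brush-border scenes, and PDB/mmCIF export.
#'
#' @keywords internal
#' @importFrom stats lm coef dist runif setNames
#' @importFrom utils write.table
"_PACKAGE"

.datatable.aware <- TRUE

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", ".I", ".N", "component", "instance", "domain", "label", "x", "y",
  "z", "r", "cx", "cy", "cz", "idx", "qidx", "comp", "qcomp", "inst",
  "qinst", "lab", "qlab", "qx", "qy", "qz", "qr", "limit", "count",
  "per10", "component_a", "instance_a", "label_a", "component_b",
  "instance_b", "label_b", "motor_instance", "iq"))
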