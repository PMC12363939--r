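# Built-in transform registration. Transforms that need a component
# dictionary read it from extras$component_dict (placed there by the
# attach_components step), so a whole pipeline stays serializable to YAML:
# every parameter is a scalar or a file path.

state_dict <- function(state, dict = NULL) {
  if (!is.null(dict)) return(dict)
  d <- state$extras$component_dict
  if (is.null(d)) stop("no component dictionary: run attach_components first ",
                       "or pass `dict`")
  d
}

register_builtin_transforms <- function() {
  register_transform("identity", function(state) state)
  register_transform("attach_components", function(state, path = NULL) {
    dict <- if (is.null(path)) builtin_components() else
      read_component_dictionary(path)
    state$extras$component_dict <- dict
    state
  }, writes = "component_dict")
  register_transform("attach_bonds", function(state, hydrogens = TRUE)
    attach_intra_component_bonds(state, state_dict(state), hydrogens),
    reads = "component_dict")
  register_transform("resolve_altlocs", resolve_altlocs)
  register_transform("detect_covalent_links",
                     function(state, infer_by_distance = FALSE, slack = 0.4)
                       detect_covalent_links(state, NULL, infer_by_distance,
                                             slack),
                     reads = "struct_conn")
  register_transform("remove_leaving_groups", function(state)
    remove_leaving_groups(state, state_dict(state)),
    reads = "component_dict")
  register_transform("correct_bond_order", function(state)
    correct_bond_order_after_addition(state, state_dict(state)),
    reads = "component_dict")
  register_transform("assign_formal_charges", function(state)
    assign_formal_charges(state, state_dict(state)),
    reads = "component_dict")
  register_transform("deduplicate_symmetry_ligands",
                     function(state, centroid_tol = 1.0)
                       deduplicate_symmetry_ligands(state, centroid_tol))
  register_transform("impute_missing", function(state)
    impute_missing_intra_residue(state, state_dict(state)),
    reads = "component_dict", writes = "imputed")
  register_transform("invert_structure", invert_structure)
  register_transform("sample_inversion_augmentation",
                     function(state, p = 0.02)
                       sample_inversion_augmentation(state, p))
  register_transform("extend_disordered_regions",
                     function(state, phi = 180, psi = 180, omega = 180,
                              clash_tol = 2.0, max_retries = 10)
                       extend_disordered_regions(
                         state, ideal_geometry(phi, psi, omega), clash_tol,
                         max_retries),
                     writes = "imputed_extended")
  register_transform("delete_chain", function(state, chain) {
    uids <- state$table$atoms$atom_uid[state$table$atoms$chain_id %in% chain]
    delete_atoms(state, uids)
  })
}

#' Standard sanitization pipeline
#'
#' The default cleanup sequence: attach component bonds, resolve altlocs,
#' materialize covalent links, remove leaving groups at linkage sites,
#' correct bond orders, assign formal charges, deduplicate symmetry-center
#' ligand copies, impute missing intra-residue coordinates.
#'
#' @param components optional component dictionary CIF path (default: the
#'   built-in fixture dictionary).
#' @param infer_covalent enable distance-based covalent-link inference.
#' @return a `Pipeline`.
#' @export
sanitize_pipeline <- function(components = NULL, infer_covalent = FALSE) {
  compose_pipeline(list(
    list(transform = "attach_components", params = list(path = components)),
    "attach_bonds",
    "resolve_altlocs",
    list(transform = "detect_covalent_links",
         params = list(infer_by_distance = infer_covalent)),
    "remove_leaving_groups",
    "correct_bond_order",
    "assign_formal_charges",
    "deduplicate_symmetry_ligands",
    "impute_missing"))
}

.onLoad <- function(libname, pkgname) {
  register_builtin_transforms()
}
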