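# Reference conformers: molecules are rebuilt from the component graph
# (atoms, bonds, formal charges — never deposited experimental
# coordinates), embedded in 3D by seeded distance-geometry (ETKDG) and
# relaxed with an empirical force field (MMFF94, falling back to UFF when a
# component is outside MMFF94's parameterization). The chemistry backend is
# RDKit, driven through a bundled helper script; energies are reported in
# kJ/mol. Stereo descriptors are taken from the component's ideal
# coordinates, so the generated conformer reproduces the template's
# chirality — which is exactly what makes correct charge and bond-order
# annotations matter: the force field sees only the graph.

KCAL_TO_KJ <- 4.184

find_python <- function() {
  p <- Sys.which("python")
  if (p == "") p <- Sys.which("python3")
  if (p == "") stop("no python interpreter on PATH; conformer generation ",
                    "requires the RDKit backend")
  p
}

conformer_backend <- function() {
  script <- system.file("python", "embed_conformer.py", package = "structforge")
  if (script == "") {
    # during in-source development
    script <- file.path("inst", "python", "embed_conformer.py")
    if (!file.exists(script)) stop("embed_conformer.py not found")
  }
  script
}

run_conformer_backend <- function(args) {
  out <- suppressWarnings(system2(find_python(),
                                  c(shQuote(conformer_backend()), args),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("conformer backend failed: ", paste(out, collapse = "; "))
  invisible(out)
}

#' Write a component graph as a MOL/SDF (V2000) block
#'
#' By default the component's ideal coordinates are written when available —
#' downstream embedding uses them only to perceive stereo descriptors, never
#' as a coordinate source. With `coords = NULL` and no ideal coordinates the
#' atoms sit at the origin and only the graph is meaningful.
#'
#' @param component a `ComponentDefinition`.
#' @param path output file path.
#' @param coords optional n x 3 matrix overriding the ideal coordinates.
#' @param drop_leaving omit leaving-flagged atoms.
#' @return invisibly, the data.frame of atoms written.
#' @export
write_component_sdf <- function(component, path, coords = NULL,
                                drop_leaving = FALSE) {
  at <- component$atoms
  keep <- if (drop_leaving) !at$is_leaving else rep(TRUE, nrow(at))
  at <- at[keep, , drop = FALSE]
  if (is.null(coords)) {
    coords <- as.matrix(at[, c("ix", "iy", "iz")])
    if (!all(is.finite(coords))) coords <- matrix(0, nrow(at), 3)
  }
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == nrow(at))
  bd <- component$bonds
  bd <- bd[bd$a %in% at$name & bd$b %in% at$name, , drop = FALSE]
  omap <- c(single = 1L, double = 2L, triple = 3L, aromatic = 4L)
  lines <- c(component$comp_id, "  structforge", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     nrow(at), nrow(bd)))
  el <- paste0(substr(at$element, 1, 1), tolower(substr(at$element, 2, 2)))
  for (i in seq_len(nrow(at)))
    lines <- c(lines, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      coords[i, 1], coords[i, 2], coords[i, 3], el[i]))
  ia <- match(bd$a, at$name); ib <- match(bd$b, at$name)
  for (i in seq_len(nrow(bd)))
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0", ia[i], ib[i],
                              omap[[bd$order[i]]]))
  chg <- which(at$charge != 0)
  if (length(chg))
    lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(chg)),
                             paste0(sprintf("%4d%4d", chg, at$charge[chg]),
                                    collapse = "")))
  lines <- c(lines, "M  END", "$$$$")
  writeLines(lines, path)
  invisible(at)
}

#' Generate a reference conformer for a component
#'
#' The molecule is rebuilt from the component graph alone: stereo
#' descriptors are perceived from the component's ideal coordinates, fresh
#' 3D coordinates are embedded by seeded distance geometry (ETKDG), and the
#' result is minimized with MMFF94 (UFF fallback). The embedded conformer's
#' stereocenters are checked against the component's ideal-coordinate
#' chirality via the chirality module and the whole conformer is mirrored
#' if the embedding picked the opposite hand (only possible for components
#' without ideal coordinates).
#'
#' @param component a sanitized `ComponentDefinition` (complete bond orders
#'   and formal charges).
#' @param seed integer seed for the embedding.
#' @param max_iter minimizer iteration cap.
#' @return `ConformerResult`: list with `comp_id`, `atoms` (name + element;
#'   generated hydrogens appended as HX1, HX2, ...), `coords` (n x 3,
#'   angstroms), `initial_energy` and `final_energy` (kJ/mol), `converged`,
#'   `forcefield`, `seed`.
#' @export
generate_reference_conformer <- function(component, seed = 1L,
                                         max_iter = 2000) {
  td <- tempfile("conf"); dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  mol <- file.path(td, "graph.mol")
  written <- write_component_sdf(component, mol)
  out_json <- file.path(td, "embed.json")
  run_conformer_backend(c("embed", shQuote(mol), shQuote(out_json),
                          as.integer(seed), as.integer(max_iter)))
  if (!file.exists(out_json))
    stop("3D embedding failed for component ", component$comp_id)
  res <- jsonlite::read_json(out_json, simplifyVector = TRUE)
  n_named <- nrow(written)
  n_total <- length(res$elements)
  atoms <- data.frame(
    name = c(written$name,
             if (n_total > n_named) paste0("HX", seq_len(n_total - n_named))
             else character()),
    element = toupper(res$elements), stringsAsFactors = FALSE)
  out <- structure(list(
    comp_id = component$comp_id, atoms = atoms,
    coords = matrix(res$coords, ncol = 3,
                    dimnames = list(atoms$name, c("x", "y", "z"))),
    initial_energy = res$initial_energy_kcal * KCAL_TO_KJ,
    final_energy = res$final_energy_kcal * KCAL_TO_KJ,
    converged = isTRUE(res$converged), forcefield = res$forcefield,
    seed = as.integer(seed)), class = "ConformerResult")
  match_component_chirality(out, component)
}

# mirror the conformer if its stereocenters disagree with the component's
# ideal-coordinate handedness (force-field energies are mirror-invariant)
match_component_chirality <- function(res, component) {
  signs <- conformer_center_signs(res, component)
  if (!nrow(signs)) return(res)
  if (all(signs$conf == signs$ideal)) return(res)
  res$coords[, 1] <- -res$coords[, 1]
  signs2 <- conformer_center_signs(res, component)
  if (!all(signs2$conf == signs2$ideal))
    warning("component ", component$comp_id,
            ": embedded diastereomer does not match the ideal coordinates ",
            "at every center")
  res
}

conformer_state <- function(res) {
  n <- nrow(res$coords)
  pipeline_state(atom_table(
    data.frame(atom_uid = seq_len(n), chain_id = "X", entity_id = 1L,
               res_index = 1L, comp_id = res$comp_id,
               atom_name = res$atoms$name, element = res$atoms$element,
               altloc = "", occupancy = 1, formal_charge = 0L,
               x = res$coords[, 1], y = res$coords[, 2], z = res$coords[, 3],
               is_resolved = TRUE, stringsAsFactors = FALSE)))
}

# signed chiral angles of the conformer vs the component ideal coordinates,
# per detectable stereocenter (matched by component atom names)
conformer_center_signs <- function(res, component) {
  st <- conformer_state(res)
  dict <- stats::setNames(list(component), component$comp_id)
  st <- attach_intra_component_bonds(st, dict)
  found <- find_chiral_centers(st, dict)
  out <- list()
  a <- st$table$atoms
  for (cc in found$centers) {
    nm <- a$atom_name[match(c(cc$center, cc$ordered_neighbors), a$atom_uid)]
    idx <- match(nm, component$atoms$name)
    if (anyNA(idx)) next
    ideal <- as.matrix(component$atoms[idx, c("ix", "iy", "iz")])
    if (!all(is.finite(ideal))) next
    xyz <- coords_matrix(st$table, c(cc$center, cc$ordered_neighbors))
    out[[length(out) + 1L]] <- data.frame(
      center = nm[1],
      conf = sign(chiral_angle(xyz[1, ], xyz[2, ], xyz[3, ], xyz[4, ])),
      ideal = sign(chiral_angle(ideal[1, ], ideal[2, ], ideal[3, ],
                                ideal[4, ])))
  }
  if (!length(out)) return(data.frame(center = character(), conf = numeric(),
                                      ideal = numeric()))
  do.call(rbind, out)
}

#' @export
print.ConformerResult <- function(x, ...) {
  cat(sprintf("ConformerResult %s: %d atoms, %s, E %0.2f -> %0.2f kJ/mol%s\n",
              x$comp_id, nrow(x$coords), x$forcefield, x$initial_energy,
              x$final_energy, if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' Single-point conformer energy
#'
#' Energy of the given coordinates under the same force field used for
#' minimization, in kJ/mol. The molecule (elements, bonds, charges,
#' generated hydrogens) is reconstructed from the `ConformerResult` and its
#' source component; pass `coords` to evaluate a modified geometry of the
#' same molecule.
#'
#' @param conformer a `ConformerResult`.
#' @param component the `ComponentDefinition` the conformer was generated
#'   from (bond-graph source).
#' @param coords optional replacement n x 3 coordinate matrix covering all
#'   atoms, hydrogens included.
#' @return energy in kJ/mol.
#' @export
conformer_energy <- function(conformer, component, coords = NULL) {
  if (is.null(coords)) coords <- conformer$coords
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(conformer$coords))
    stop("coords must cover all ", nrow(conformer$coords), " atoms (",
         paste(utils::head(conformer$atoms$name, 3), collapse = ", "),
         ", ...)")
  td <- tempfile("spe"); dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  mol <- file.path(td, "mol.mol")
  write_full_conformer_sdf(conformer, component, coords, mol)
  out_json <- file.path(td, "energy.json")
  run_conformer_backend(c("energy", shQuote(mol), shQuote(out_json)))
  if (!file.exists(out_json))
    stop("force-field energy evaluation failed for ", conformer$comp_id)
  res <- jsonlite::read_json(out_json, simplifyVector = TRUE)
  res$energy_kcal * KCAL_TO_KJ
}

# MOL block of the conformer including generated hydrogens; bonds among the
# named atoms come from the component, generated hydrogens are attached to
# their nearest heavy atom (how the embedding created them)
write_full_conformer_sdf <- function(conformer, component, coords, path) {
  at <- conformer$atoms
  omap <- c(single = 1L, double = 2L, triple = 3L, aromatic = 4L)
  bd <- component$bonds
  ia <- match(bd$a, at$name); ib <- match(bd$b, at$name)
  ok <- !is.na(ia) & !is.na(ib)
  bonds <- cbind(ia[ok], ib[ok], unname(omap[bd$order[ok]]))
  extra_h <- which(is.na(match(at$name, component$atoms$name)))
  heavy <- which(!(at$element %in% c("H", "D")))
  for (h in extra_h) {
    d2 <- rowSums(sweep(coords[heavy, , drop = FALSE], 2, coords[h, ])^2)
    bonds <- rbind(bonds, c(heavy[which.min(d2)], h, 1L))
  }
  chg_idx <- match(component$atoms$name, at$name)
  lines <- c(conformer$comp_id, "  structforge", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     nrow(at), nrow(bonds)))
  el <- paste0(substr(at$element, 1, 1), tolower(substr(at$element, 2, 2)))
  for (i in seq_len(nrow(at)))
    lines <- c(lines, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      coords[i, 1], coords[i, 2], coords[i, 3], el[i]))
  for (i in seq_len(nrow(bonds)))
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0", bonds[i, 1],
                              bonds[i, 2], bonds[i, 3]))
  nz <- which(component$atoms$charge != 0 & !is.na(chg_idx))
  if (length(nz))
    lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(nz)),
                             paste0(sprintf("%4d%4d", chg_idx[nz],
                                            component$atoms$charge[nz]),
                                    collapse = "")))
  lines <- c(lines, "M  END", "$$$$")
  writeLines(lines, path)
}
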