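# mmCIF / PDB / component-dictionary ingestion into the AtomTable
# representation, and mmCIF export.

KNOWN_ELEMENTS <- c("H", "D", "HE", "LI", "BE", "B", "C", "N", "O", "F", "NE",
                    "NA", "MG", "AL", "SI", "P", "S", "CL", "AR", "K", "CA",
                    "MN", "FE", "CO", "NI", "CU", "ZN", "SE", "BR", "I", "MO",
                    "W", "V", "CR", "AS", "CD", "HG", "PT", "AU", "RU", "SR",
                    "CS", "BA", "RB", "LI", "GA", "GE", "SN", "PB", "TI")

BACKBONE_PROTEIN <- c("N", "CA", "C", "O")
BACKBONE_NUCLEIC <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'",
                      "O3'", "C2'", "C1'")

num_or_na <- function(x) suppressWarnings(as.numeric(x))
int_or_na <- function(x) suppressWarnings(as.integer(x))

#' Read an mmCIF structure file
#'
#' Builds a [pipeline_state()] from the `atom_site` category: one atom per
#' record, altlocs preserved, stable `atom_uid`s assigned in file order.
#' Polymer residues listed in `entity_poly_seq` but absent from `atom_site`
#' are appended as placeholder atoms with `is_resolved = FALSE` and missing
#' coordinates, so downstream imputation and disorder extension have slots to
#' fill. `struct_conn` records are parsed into `extras$struct_conn` (they
#' become bonds via [detect_covalent_links()]).
#'
#' @param path mmCIF file path.
#' @param components optional component dictionary from
#'   [read_component_dictionary()]; when given, placeholder atoms for
#'   unresolved residues carry the component's full heavy-atom set, otherwise
#'   the four protein backbone atoms.
#' @return a `PipelineState`.
#' @export
read_mmcif <- function(path, components = NULL) {
  cats <- read_cif_categories(path)
  as_df <- cats$atom_site
  if (is.null(as_df) || !nrow(as_df))
    stop("not a structure mmCIF: no atom_site category in ", path)
  col <- function(nm, default = NA_character_) {
    if (nm %in% names(as_df)) as_df[[nm]] else rep(default, nrow(as_df))
  }
  element <- toupper(col("type_symbol"))
  bad <- !is.na(element) & !(element %in% KNOWN_ELEMENTS)
  if (any(bad))
    stop("unknown element symbol '", element[which(bad)[1]], "' in atom_site row ",
         which(bad)[1])
  atoms <- data.frame(
    atom_uid = seq_len(nrow(as_df)),
    chain_id = col("label_asym_id"),
    entity_id = int_or_na(col("label_entity_id", "1")),
    res_index = int_or_na(col("label_seq_id")),
    comp_id = col("label_comp_id"),
    atom_name = col("label_atom_id"),
    element = element,
    altloc = ifelse(is.na(col("label_alt_id")), "", col("label_alt_id")),
    occupancy = num_or_na(col("occupancy", "1")),
    formal_charge = int_or_na(col("pdbx_formal_charge", "0")),
    x = num_or_na(col("Cartn_x")), y = num_or_na(col("Cartn_y")),
    z = num_or_na(col("Cartn_z")),
    is_resolved = TRUE, stringsAsFactors = FALSE)
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  atoms$formal_charge[is.na(atoms$formal_charge)] <- 0L
  # non-polymer rows have label_seq_id "."; give each its own index from auth
  if (anyNA(atoms$res_index)) {
    auth <- int_or_na(col("auth_seq_id"))
    atoms$res_index[is.na(atoms$res_index)] <-
      ifelse(is.na(auth[is.na(atoms$res_index)]), 1L, auth[is.na(atoms$res_index)])
  }
  atoms$auth_res_index <- int_or_na(col("auth_seq_id"))
  extras <- list()
  # unresolved polymer residues -> placeholder atoms
  eps <- cats$entity_poly_seq
  if (!is.null(eps) && nrow(eps)) {
    eps$entity_id <- int_or_na(eps$entity_id)
    eps$num <- int_or_na(eps$num)
    chain_of_entity <- unique(atoms[, c("chain_id", "entity_id")])
    placeholders <- list()
    for (r in seq_len(nrow(eps))) {
      chains <- chain_of_entity$chain_id[chain_of_entity$entity_id == eps$entity_id[r]]
      for (ch in chains) {
        present <- any(atoms$chain_id == ch & atoms$res_index == eps$num[r] &
                         atoms$comp_id == eps$mon_id[r])
        if (present) next
        nm <- placeholder_atom_names(eps$mon_id[r], components)
        placeholders[[length(placeholders) + 1L]] <- data.frame(
          atom_uid = NA_integer_, chain_id = ch, entity_id = eps$entity_id[r],
          res_index = eps$num[r], comp_id = eps$mon_id[r], atom_name = nm$name,
          element = nm$element, altloc = "", occupancy = 0,
          formal_charge = 0L, x = NA_real_, y = NA_real_, z = NA_real_,
          is_resolved = FALSE, auth_res_index = NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
    if (length(placeholders)) {
      ph <- do.call(rbind, placeholders)
      ph$atom_uid <- max(atoms$atom_uid) + seq_len(nrow(ph))
      atoms <- rbind(atoms, ph)
    }
  }
  # struct_conn records kept as annotations until detect_covalent_links
  sc <- cats$struct_conn
  if (!is.null(sc) && nrow(sc)) {
    g <- function(nm) if (nm %in% names(sc)) sc[[nm]] else rep(NA_character_, nrow(sc))
    extras$struct_conn <- data.frame(
      conn_type = g("conn_type_id"),
      chain1 = g("ptnr1_label_asym_id"), res1 = int_or_na(g("ptnr1_label_seq_id")),
      comp1 = g("ptnr1_label_comp_id"), atom1 = g("ptnr1_label_atom_id"),
      chain2 = g("ptnr2_label_asym_id"), res2 = int_or_na(g("ptnr2_label_seq_id")),
      comp2 = g("ptnr2_label_comp_id"), atom2 = g("ptnr2_label_atom_id"),
      order = g("pdbx_value_order"), stringsAsFactors = FALSE)
    # ligand partners may carry no label_seq_id; fall back to auth numbering
    for (side in 1:2) {
      rc <- paste0("res", side)
      auth <- int_or_na(g(paste0("ptnr", side, "_auth_seq_id")))
      extras$struct_conn[[rc]][is.na(extras$struct_conn[[rc]])] <-
        auth[is.na(extras$struct_conn[[rc]])]
    }
  }
  auth <- atoms$auth_res_index
  atoms$auth_res_index <- NULL
  st <- pipeline_state(atom_table(atoms), extras = extras)
  st$extras$auth_res_index <- stats::setNames(auth, atoms$atom_uid)
  st
}

placeholder_atom_names <- function(comp_id, components) {
  if (!is.null(components) && comp_id %in% names(components)) {
    at <- components[[comp_id]]$atoms
    heavy <- at[!(toupper(at$element) %in% c("H", "D")) & !at$is_leaving, ,
                drop = FALSE]
    return(list(name = heavy$name, element = toupper(heavy$element)))
  }
  list(name = BACKBONE_PROTEIN, element = c("N", "C", "C", "O"))
}

#' Write a pipeline state to mmCIF
#'
#' Emits `atom_site` for resolved atoms (placeholders are omitted, matching
#' deposition conventions), `entity_poly_seq` for multi-residue chains so
#' unresolved residues survive a round trip, and one `struct_conn` row per
#' inter-residue covalent bond of provenance `struct_conn` or `inferred`.
#'
#' @param state a `PipelineState`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mmcif <- function(state, path) {
  stopifnot(inherits(state, "PipelineState"))
  a <- state$table$atoms
  res <- a[a$is_resolved, , drop = FALSE]
  if (!nrow(res)) stop("write_mmcif: no resolved atoms to write")
  cats <- list()
  cats$atom_site <- data.frame(
    group_PDB = ifelse(is_polymer_comp(res$comp_id), "ATOM", "HETATM"),
    id = res$atom_uid, type_symbol = res$element,
    label_atom_id = res$atom_name,
    label_alt_id = ifelse(res$altloc == "", ".", res$altloc),
    label_comp_id = res$comp_id, label_asym_id = res$chain_id,
    label_entity_id = res$entity_id, label_seq_id = res$res_index,
    Cartn_x = sprintf("%.3f", res$x), Cartn_y = sprintf("%.3f", res$y),
    Cartn_z = sprintf("%.3f", res$z),
    occupancy = sprintf("%.2f", res$occupancy),
    pdbx_formal_charge = res$formal_charge,
    auth_seq_id = res$res_index, auth_asym_id = res$chain_id,
    stringsAsFactors = FALSE)
  # polymer chains: any chain of an entity with >= 2 distinct residue indices
  poly <- unique(a[, c("chain_id", "entity_id", "res_index", "comp_id")])
  nres <- tapply(poly$res_index, poly$entity_id, function(v) length(unique(v)))
  poly_ent <- as.integer(names(nres)[nres >= 2])
  eps <- poly[poly$entity_id %in% poly_ent, , drop = FALSE]
  if (nrow(eps)) {
    eps <- unique(eps[, c("entity_id", "res_index", "comp_id")])
    eps <- eps[order(eps$entity_id, eps$res_index), ]
    cats$entity_poly_seq <- data.frame(entity_id = eps$entity_id,
                                       num = eps$res_index,
                                       mon_id = eps$comp_id,
                                       stringsAsFactors = FALSE)
  }
  b <- state$table$bonds
  if (nrow(b)) {
    ia <- match(b$atom_a, a$atom_uid); ib <- match(b$atom_b, a$atom_uid)
    inter <- residue_key(a[ia, ]) != residue_key(a[ib, ])
    keep <- inter & b$provenance %in% c("struct_conn", "inferred") &
      a$is_resolved[ia] & a$is_resolved[ib]
    # polymer backbone links are implied by entity_poly_seq, not struct_conn
    bb <- (a$atom_name[ia] == "C" & a$atom_name[ib] == "N") |
      (a$atom_name[ia] == "N" & a$atom_name[ib] == "C") |
      (a$atom_name[ia] == "O3'" & a$atom_name[ib] == "P") |
      (a$atom_name[ia] == "P" & a$atom_name[ib] == "O3'")
    adjacent <- a$chain_id[ia] == a$chain_id[ib] &
      abs(a$res_index[ia] - a$res_index[ib]) == 1L
    keep <- keep & !(bb & adjacent)
    if (any(keep)) {
      ka <- ia[keep]; kb <- ib[keep]
      disulf <- a$element[ka] == "S" & a$element[kb] == "S"
      cats$struct_conn <- data.frame(
        id = paste0(ifelse(disulf, "disulf", "covale"), seq_len(sum(keep))),
        conn_type_id = ifelse(disulf, "disulf", "covale"),
        ptnr1_label_asym_id = a$chain_id[ka], ptnr1_label_seq_id = a$res_index[ka],
        ptnr1_label_comp_id = a$comp_id[ka], ptnr1_label_atom_id = a$atom_name[ka],
        ptnr2_label_asym_id = a$chain_id[kb], ptnr2_label_seq_id = a$res_index[kb],
        ptnr2_label_comp_id = a$comp_id[kb], ptnr2_label_atom_id = a$atom_name[kb],
        pdbx_value_order = b$order[keep], stringsAsFactors = FALSE)
    }
  }
  write_cif_categories(cats, path)
}

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
                 "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
                 "TYR", "VAL")
STANDARD_NUC <- c("A", "C", "G", "U", "DA", "DC", "DG", "DT")

is_polymer_comp <- function(comp_id) comp_id %in% c(STANDARD_AA, STANDARD_NUC)

#' Read a PDB-format file (read-only)
#'
#' Parses coordinates through `bio3d::read.pdb` and converts to the atom
#' table; SSBOND and LINK records are scanned from the raw text into
#' `extras$struct_conn`. No other inter-residue inference is performed.
#'
#' @param path PDB file path.
#' @return a `PipelineState`.
#' @export
read_pdb_file <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  atoms <- data.frame(
    atom_uid = seq_len(nrow(at)), chain_id = at$chain,
    entity_id = as.integer(factor(at$chain)), res_index = at$resno,
    comp_id = at$resid, atom_name = at$elety,
    element = toupper(ifelse(is.na(at$elesy) | at$elesy == "",
                             substr(trimws(at$elety), 1, 1), at$elesy)),
    altloc = ifelse(is.na(at$alt) | at$alt == "", "", at$alt),
    occupancy = ifelse(is.na(at$o), 1, pmin(1, pmax(0, at$o))),
    formal_charge = 0L, x = at$x, y = at$y, z = at$z,
    is_resolved = TRUE, stringsAsFactors = FALSE)
  extras <- list()
  raw <- readLines(path, warn = FALSE)
  ss <- raw[startsWith(raw, "SSBOND")]
  lk <- raw[startsWith(raw, "LINK")]
  recs <- list()
  for (ln in ss) recs[[length(recs) + 1L]] <- data.frame(
    conn_type = "disulf",
    chain1 = substr(ln, 16, 16), res1 = int_or_na(substr(ln, 18, 21)),
    comp1 = trimws(substr(ln, 12, 14)), atom1 = "SG",
    chain2 = substr(ln, 30, 30), res2 = int_or_na(substr(ln, 32, 35)),
    comp2 = trimws(substr(ln, 26, 28)), atom2 = "SG",
    order = NA_character_, stringsAsFactors = FALSE)
  for (ln in lk) recs[[length(recs) + 1L]] <- data.frame(
    conn_type = "covale",
    chain1 = substr(ln, 22, 22), res1 = int_or_na(substr(ln, 23, 26)),
    comp1 = trimws(substr(ln, 18, 20)), atom1 = trimws(substr(ln, 13, 16)),
    chain2 = substr(ln, 52, 52), res2 = int_or_na(substr(ln, 53, 56)),
    comp2 = trimws(substr(ln, 48, 50)), atom2 = trimws(substr(ln, 43, 46)),
    order = NA_character_, stringsAsFactors = FALSE)
  if (length(recs)) extras$struct_conn <- do.call(rbind, recs)
  pipeline_state(atom_table(atoms), extras = extras)
}

#' Read a CCD-style chemical component dictionary
#'
#' Parses `chem_comp_atom` and `chem_comp_bond` categories into one
#' `ComponentDefinition` per component: atom names, elements, formal charges,
#' ideal coordinates, leaving-atom flags, and bonds with orders and
#' aromaticity.
#'
#' @param path CIF file path.
#' @return named list of `ComponentDefinition` objects keyed by comp_id;
#'   empty list (with a warning) for a file with no components.
#' @export
read_component_dictionary <- function(path) {
  cats <- read_cif_categories(path)
  ca <- cats$chem_comp_atom
  if (is.null(ca) || !nrow(ca)) {
    warning("no chem_comp_atom records in ", path)
    return(list())
  }
  cb <- cats$chem_comp_bond
  out <- list()
  for (cid in unique(ca$comp_id)) {
    rows <- ca[ca$comp_id == cid, , drop = FALSE]
    g <- function(nm, def) if (nm %in% names(rows)) rows[[nm]] else rep(def, nrow(rows))
    atoms <- data.frame(
      name = rows$atom_id, element = toupper(rows$type_symbol),
      charge = int_or_na(g("charge", "0")),
      ix = num_or_na(g("pdbx_model_Cartn_x_ideal", NA)),
      iy = num_or_na(g("pdbx_model_Cartn_y_ideal", NA)),
      iz = num_or_na(g("pdbx_model_Cartn_z_ideal", NA)),
      is_leaving = toupper(g("pdbx_leaving_atom_flag", "N")) %in% "Y",
      stringsAsFactors = FALSE)
    atoms$charge[is.na(atoms$charge)] <- 0L
    if (anyDuplicated(atoms$name))
      stop("component ", cid, ": duplicate atom name")
    bonds <- data.frame(a = character(), b = character(), order = character(),
                        aromatic = logical(), stringsAsFactors = FALSE)
    if (!is.null(cb)) {
      br <- cb[cb$comp_id == cid, , drop = FALSE]
      if (nrow(br)) {
        unknown <- setdiff(c(br$atom_id_1, br$atom_id_2), atoms$name)
        if (length(unknown))
          stop("component ", cid, ": bond references unknown atom ",
               paste(unknown, collapse = ", "))
        omap <- c(SING = "single", DOUB = "double", TRIP = "triple",
                  AROM = "aromatic")
        bonds <- data.frame(
          a = br$atom_id_1, b = br$atom_id_2,
          order = unname(omap[toupper(br$value_order)]),
          aromatic = toupper(if ("pdbx_aromatic_flag" %in% names(br))
            br$pdbx_aromatic_flag else rep("N", nrow(br))) %in% "Y",
          stringsAsFactors = FALSE)
        bonds$order[is.na(bonds$order)] <- "single"
      }
    }
    out[[cid]] <- structure(list(comp_id = cid, atoms = atoms, bonds = bonds),
                            class = "ComponentDefinition")
  }
  out
}

#' @export
print.ComponentDefinition <- function(x, ...) {
  cat(sprintf("ComponentDefinition %s: %d atoms (%d leaving), %d bonds\n",
              x$comp_id, nrow(x$atoms), sum(x$atoms$is_leaving), nrow(x$bonds)))
  invisible(x)
}

#' Attach intra-component and polymer backbone bonds
#'
#' For every residue, adds the bonds declared in its component definition
#' between atoms actually present in the table (absent atoms never yield
#' dangling bonds), provenance `intra_component`. Consecutive residues in a
#' chain are joined by the polymer backbone bond (peptide C-N or nucleic
#' O3'-P), provenance `inferred`.
#'
#' @param state a `PipelineState`.
#' @param dict component dictionary from [read_component_dictionary()].
#' @param hydrogens attach bonds to hydrogens too (default TRUE).
#' @return the updated state.
#' @export
attach_intra_component_bonds <- function(state, dict, hydrogens = TRUE) {
  a <- state$table$atoms
  missing_comp <- setdiff(unique(a$comp_id), names(dict))
  if (length(missing_comp))
    stop("no component definition for: ", paste(missing_comp, collapse = ", "))
  new_bonds <- list()
  for (key in unique(residue_key(a))) {
    rows <- a[residue_key(a) == key, , drop = FALSE]
    def <- dict[[rows$comp_id[1]]]
    if (!nrow(def$bonds)) next
    uid_of <- stats::setNames(rows$atom_uid, rows$atom_name)
    bb <- def$bonds
    ua <- uid_of[bb$a]; ub <- uid_of[bb$b]
    ok <- !is.na(ua) & !is.na(ub)
    if (any(ok)) new_bonds[[length(new_bonds) + 1L]] <- data.frame(
      atom_a = unname(ua[ok]), atom_b = unname(ub[ok]),
      order = ifelse(bb$aromatic[ok], "aromatic", bb$order[ok]),
      provenance = "intra_component", stringsAsFactors = FALSE)
  }
  # polymer backbone links between consecutive residues of a chain
  for (ch in unique(a$chain_id)) {
    ca <- a[a$chain_id == ch, , drop = FALSE]
    idx <- sort(unique(ca$res_index))
    if (length(idx) < 2L) next
    for (i in seq_len(length(idx) - 1L)) {
      if (idx[i + 1L] != idx[i] + 1L) next
      r1 <- ca[ca$res_index == idx[i], , drop = FALSE]
      r2 <- ca[ca$res_index == idx[i + 1L], , drop = FALSE]
      pair <- NULL
      if ("C" %in% r1$atom_name && "N" %in% r2$atom_name)
        pair <- c(r1$atom_uid[r1$atom_name == "C"][1],
                  r2$atom_uid[r2$atom_name == "N"][1])
      else if ("O3'" %in% r1$atom_name && "P" %in% r2$atom_name)
        pair <- c(r1$atom_uid[r1$atom_name == "O3'"][1],
                  r2$atom_uid[r2$atom_name == "P"][1])
      if (!is.null(pair)) new_bonds[[length(new_bonds) + 1L]] <- data.frame(
        atom_a = pair[1], atom_b = pair[2], order = "single",
        provenance = "inferred", stringsAsFactors = FALSE)
    }
  }
  if (length(new_bonds)) {
    nb <- do.call(rbind, new_bonds)
    if (!hydrogens) {
      el <- stats::setNames(a$element, a$atom_uid)
      hy <- el[as.character(nb$atom_a)] %in% c("H", "D") |
        el[as.character(nb$atom_b)] %in% c("H", "D")
      nb <- nb[!hy, , drop = FALSE]
    }
    all_b <- rbind(state$table$bonds, nb)
    pk <- paste(pmin(all_b$atom_a, all_b$atom_b), pmax(all_b$atom_a, all_b$atom_b))
    state$table$bonds <- all_b[!duplicated(pk), , drop = FALSE]
  }
  validate_atom_table(state$table)
  state
}
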