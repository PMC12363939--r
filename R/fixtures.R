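# Synthetic fixtures: a mini component dictionary built in code (CCD
# conventions: ideal coordinates, leaving flags, bond orders), toy peptides
# with optional D-residues, pathological single-rule structures, and seeded
# coordinate perturbation. Everything regenerates bit-identically from
# (spec, seed); no downloads.

make_component <- function(comp_id, atoms, bonds) {
  atoms$charge <- as.integer(atoms$charge)
  structure(list(comp_id = comp_id,
                 atoms = as.data.frame(atoms, stringsAsFactors = FALSE),
                 bonds = as.data.frame(bonds, stringsAsFactors = FALSE)),
            class = "ComponentDefinition")
}

comp_atom <- function(name, element, xyz = c(NA, NA, NA), charge = 0L,
                      leaving = FALSE) {
  data.frame(name = name, element = element, charge = as.integer(charge),
             ix = xyz[1], iy = xyz[2], iz = xyz[3], is_leaving = leaving,
             stringsAsFactors = FALSE)
}

comp_bond <- function(a, b, order = "single", aromatic = FALSE) {
  data.frame(a = a, b = b, order = order, aromatic = aromatic,
             stringsAsFactors = FALSE)
}

# ideal backbone frame shared by the amino-acid components
aa_backbone_ideal <- function() {
  g <- ideal_geometry()
  N <- c(0, 0, 0)
  CA <- c(g$len_n_ca, 0, 0)
  ang <- g$ang_n_ca_c * pi / 180
  C <- CA + g$len_ca_c * c(-cos(ang), sin(ang), 0)
  O <- place_atom(N, CA, C, g$len_c_o, g$ang_ca_c_o, 0)
  OXT <- place_atom(N, CA, C, 1.25, g$ang_ca_c_o, 180)
  list(N = N, CA = CA, C = C, O = O, OXT = OXT, g = g)
}

# L-configured CB: improper dihedral C-N-CA-CB fixed at -122.6 degrees,
# which reproduces the standard L-amino-acid hand under this package's
# signed-angle convention (the D form is the local mirror).
AA_CB_IMPROPER <- -122.6

aa_side_chain_base <- function(bb) {
  CB <- place_atom(bb$C, bb$N, bb$CA, 1.53, 110.5, AA_CB_IMPROPER)
  HA <- place_atom(bb$C, bb$N, bb$CA, 1.09, 108.9, AA_CB_IMPROPER + 119)
  list(CB = CB, HA = HA)
}

aa_common_atoms <- function(bb, extra_h = TRUE) {
  H <- place_atom(bb$CA, bb$C, bb$N, 1.01, 119, 180)  # amide H approx
  H2 <- place_atom(bb$CA, bb$C, bb$N, 1.01, 119, 0)
  HXT <- place_atom(bb$CA, bb$C, bb$OXT, 0.97, 110, 180)
  rbind(
    comp_atom("N", "N", bb$N), comp_atom("CA", "C", bb$CA),
    comp_atom("C", "C", bb$C), comp_atom("O", "O", bb$O),
    comp_atom("OXT", "O", bb$OXT, leaving = TRUE),
    comp_atom("H", "H", H),
    comp_atom("H2", "H", H2, leaving = TRUE),
    comp_atom("HXT", "H", HXT, leaving = TRUE))
}

aa_common_bonds <- function() {
  rbind(comp_bond("N", "CA"), comp_bond("CA", "C"),
        comp_bond("C", "O", "double"), comp_bond("C", "OXT"),
        comp_bond("N", "H"), comp_bond("N", "H2"), comp_bond("OXT", "HXT"))
}

build_ala <- function() {
  bb <- aa_backbone_ideal()
  sc <- aa_side_chain_base(bb)
  hb <- lapply(c(60, 180, 300), function(t)
    place_atom(bb$N, bb$CA, sc$CB, 1.09, 109.5, t))
  atoms <- rbind(aa_common_atoms(bb),
                 comp_atom("CB", "C", sc$CB), comp_atom("HA", "H", sc$HA),
                 comp_atom("HB1", "H", hb[[1]]), comp_atom("HB2", "H", hb[[2]]),
                 comp_atom("HB3", "H", hb[[3]]))
  bonds <- rbind(aa_common_bonds(), comp_bond("CA", "CB"),
                 comp_bond("CA", "HA"), comp_bond("CB", "HB1"),
                 comp_bond("CB", "HB2"), comp_bond("CB", "HB3"))
  make_component("ALA", atoms, bonds)
}

build_gly <- function() {
  bb <- aa_backbone_ideal()
  HA2 <- place_atom(bb$C, bb$N, bb$CA, 1.09, 110.5, AA_CB_IMPROPER)
  HA3 <- place_atom(bb$C, bb$N, bb$CA, 1.09, 110.5, AA_CB_IMPROPER + 119)
  atoms <- rbind(aa_common_atoms(bb),
                 comp_atom("HA2", "H", HA2), comp_atom("HA3", "H", HA3))
  bonds <- rbind(aa_common_bonds(), comp_bond("CA", "HA2"),
                 comp_bond("CA", "HA3"))
  make_component("GLY", atoms, bonds)
}

build_thiol_serine <- function(comp_id, elem, len) {
  bb <- aa_backbone_ideal()
  sc <- aa_side_chain_base(bb)
  gamma_name <- if (comp_id == "CYS") "SG" else "OG"
  G <- place_atom(bb$N, bb$CA, sc$CB, len, 114.0, 180)
  HB2 <- place_atom(bb$N, bb$CA, sc$CB, 1.09, 109.5, 60)
  HB3 <- place_atom(bb$N, bb$CA, sc$CB, 1.09, 109.5, 300)
  HG <- place_atom(bb$CA, sc$CB, G, 1.0, 96, 180)
  atoms <- rbind(aa_common_atoms(bb),
                 comp_atom("CB", "C", sc$CB), comp_atom("HA", "H", sc$HA),
                 comp_atom(gamma_name, elem, G),
                 comp_atom("HB2", "H", HB2), comp_atom("HB3", "H", HB3),
                 comp_atom("HG", "H", HG))
  bonds <- rbind(aa_common_bonds(), comp_bond("CA", "CB"),
                 comp_bond("CA", "HA"), comp_bond("CB", gamma_name),
                 comp_bond("CB", "HB2"), comp_bond("CB", "HB3"),
                 comp_bond(gamma_name, "HG"))
  make_component(comp_id, atoms, bonds)
}

build_hoh <- function() {
  atoms <- rbind(comp_atom("O", "O", c(0, 0, 0)),
                 comp_atom("H1", "H", c(0.96, 0, 0)),
                 comp_atom("H2", "H", c(-0.24, 0.93, 0)))
  bonds <- rbind(comp_bond("O", "H1"), comp_bond("O", "H2"))
  make_component("HOH", atoms, bonds)
}

build_act <- function() {
  # acetate anion: CH3-C(=O)O(-)
  C <- c(0, 0, 0)
  CH3 <- c(1.50, 0, 0)
  O <- place_atom(CH3 + c(0, 1, 0), CH3, C, 1.25, 120, 0)
  OXT <- place_atom(CH3 + c(0, 1, 0), CH3, C, 1.25, 120, 180)
  hs <- lapply(c(60, 180, 300), function(t)
    place_atom(O, C, CH3, 1.09, 109.5, t))
  atoms <- rbind(comp_atom("C", "C", C), comp_atom("CH3", "C", CH3),
                 comp_atom("O", "O", O),
                 comp_atom("OXT", "O", OXT, charge = -1L),
                 comp_atom("H1", "H", hs[[1]]), comp_atom("H2", "H", hs[[2]]),
                 comp_atom("H3", "H", hs[[3]]))
  bonds <- rbind(comp_bond("C", "CH3"), comp_bond("C", "O", "double"),
                 comp_bond("C", "OXT"), comp_bond("CH3", "H1"),
                 comp_bond("CH3", "H2"), comp_bond("CH3", "H3"))
  make_component("ACT", atoms, bonds)
}

build_eth <- function() {
  # ethanol with explicit hydrogens
  C1 <- c(0, 0, 0); C2 <- c(1.51, 0, 0)
  O <- place_atom(c(0, 1, 0), C1, C2, 1.43, 109.5, 60)
  hs1 <- lapply(c(60, 180, 300), function(t)
    place_atom(O, C2, C1, 1.09, 109.5, t))
  hs2 <- lapply(c(180, 300), function(t)
    place_atom(C1 + c(0, 0, 1), C1, C2, 1.09, 109.5, t))
  HO <- place_atom(C1, C2, O, 0.97, 108.5, 180)
  atoms <- rbind(comp_atom("C1", "C", C1), comp_atom("C2", "C", C2),
                 comp_atom("O1", "O", O),
                 comp_atom("H11", "H", hs1[[1]]), comp_atom("H12", "H", hs1[[2]]),
                 comp_atom("H13", "H", hs1[[3]]),
                 comp_atom("H21", "H", hs2[[1]]), comp_atom("H22", "H", hs2[[2]]),
                 comp_atom("HO1", "H", HO))
  bonds <- rbind(comp_bond("C1", "C2"), comp_bond("C2", "O1"),
                 comp_bond("C1", "H11"), comp_bond("C1", "H12"),
                 comp_bond("C1", "H13"), comp_bond("C2", "H21"),
                 comp_bond("C2", "H22"), comp_bond("O1", "HO1"))
  make_component("ETH", atoms, bonds)
}

build_trl <- function() {
  # toy tri-stereocenter ligand: CH3-CHF-CHCl-CH(OH)-CH3 backbone zig-zag
  gl <- 1.53
  C1 <- c(0, 0, 0); C2 <- c(gl, 0, 0)
  C3 <- place_atom(C1 + c(0, 0, 1), C1, C2, gl, 111, 120)
  C4 <- place_atom(C1, C2, C3, gl, 111, 180)
  C5 <- place_atom(C2, C3, C4, gl, 111, 180)
  F2 <- place_atom(C3, C1, C2, 1.38, 109.5, 120)  # improper-style placement
  H2 <- place_atom(C3, C1, C2, 1.09, 109.5, 240)
  CL3 <- place_atom(C4, C2, C3, 1.79, 109.5, 120)
  H3 <- place_atom(C4, C2, C3, 1.09, 109.5, 240)
  O4 <- place_atom(C5, C3, C4, 1.42, 109.5, 120)
  H4 <- place_atom(C5, C3, C4, 1.09, 109.5, 240)
  HO4 <- place_atom(C3, C4, O4, 0.97, 108.5, 180)
  h1 <- lapply(c(60, 180, 300), function(t)
    place_atom(C3, C2, C1, 1.09, 109.5, t))
  h5 <- lapply(c(60, 180, 300), function(t)
    place_atom(C3, C4, C5, 1.09, 109.5, t))
  atoms <- rbind(comp_atom("C1", "C", C1), comp_atom("C2", "C", C2),
                 comp_atom("C3", "C", C3), comp_atom("C4", "C", C4),
                 comp_atom("C5", "C", C5), comp_atom("F2", "F", F2),
                 comp_atom("CL3", "CL", CL3), comp_atom("O4", "O", O4),
                 comp_atom("H2", "H", H2), comp_atom("H3", "H", H3),
                 comp_atom("H4", "H", H4), comp_atom("HO4", "H", HO4),
                 comp_atom("H11", "H", h1[[1]]), comp_atom("H12", "H", h1[[2]]),
                 comp_atom("H13", "H", h1[[3]]),
                 comp_atom("H51", "H", h5[[1]]), comp_atom("H52", "H", h5[[2]]),
                 comp_atom("H53", "H", h5[[3]]))
  bonds <- rbind(comp_bond("C1", "C2"), comp_bond("C2", "C3"),
                 comp_bond("C3", "C4"), comp_bond("C4", "C5"),
                 comp_bond("C2", "F2"), comp_bond("C3", "CL3"),
                 comp_bond("C4", "O4"), comp_bond("C2", "H2"),
                 comp_bond("C3", "H3"), comp_bond("C4", "H4"),
                 comp_bond("O4", "HO4"),
                 comp_bond("C1", "H11"), comp_bond("C1", "H12"),
                 comp_bond("C1", "H13"), comp_bond("C5", "H51"),
                 comp_bond("C5", "H52"), comp_bond("C5", "H53"))
  make_component("TRL", atoms, bonds)
}

build_lg1 <- function() {
  # small covalent binder: link site C1 carries one leaving H
  C1 <- c(0, 0, 0); C2 <- c(1.52, 0, 0)
  O2 <- place_atom(C1 + c(0, 0, 1), C1, C2, 1.43, 109.5, 180)
  H1a <- place_atom(O2, C2, C1, 1.09, 109.5, 60)
  H1b <- place_atom(O2, C2, C1, 1.09, 109.5, 180)
  H1c <- place_atom(O2, C2, C1, 1.09, 109.5, 300)
  H2a <- place_atom(C1 + c(0, 1, 0), C1, C2, 1.09, 109.5, 60)
  HO2 <- place_atom(C1, C2, O2, 0.97, 108.5, 180)
  atoms <- rbind(comp_atom("C1", "C", C1), comp_atom("C2", "C", C2),
                 comp_atom("O2", "O", O2),
                 comp_atom("H1", "H", H1a, leaving = TRUE),
                 comp_atom("H1B", "H", H1b), comp_atom("H1C", "H", H1c),
                 comp_atom("H2A", "H", H2a), comp_atom("HO2", "H", HO2))
  bonds <- rbind(comp_bond("C1", "C2"), comp_bond("C2", "O2"),
                 comp_bond("C1", "H1"), comp_bond("C1", "H1B"),
                 comp_bond("C1", "H1C"), comp_bond("C2", "H2A"),
                 comp_bond("O2", "HO2"))
  make_component("LG1", atoms, bonds)
}

build_ket <- function() {
  # 2-butanone-like: carbonyl C1 is the nucleophilic-addition site
  C1 <- c(0, 0, 0)
  O1 <- c(0, 1.22, 0)
  C2 <- c(1.31, -0.75, 0)
  C3 <- c(-1.31, -0.75, 0)
  C4 <- place_atom(O1, C1, C2, 1.53, 111, 120)
  atoms <- rbind(comp_atom("C1", "C", C1), comp_atom("O1", "O", O1),
                 comp_atom("C2", "C", C2), comp_atom("C3", "C", C3),
                 comp_atom("C4", "C", C4))
  bonds <- rbind(comp_bond("C1", "O1", "double"), comp_bond("C1", "C2"),
                 comp_bond("C1", "C3"), comp_bond("C2", "C4"))
  make_component("KET", atoms, bonds)
}

#' Built-in mini component dictionary
#'
#' About ten components mirroring CCD conventions (ideal coordinates,
#' leaving flags on polymerization atoms, kekulized bond orders): ALA, GLY,
#' CYS, SER, water, acetate, ethanol, a covalent binder with a leaving
#' hydrogen at the link atom (LG1), a ketone whose carbonyl carbon is a
#' nucleophilic-addition site (KET), and a three-stereocenter ligand (TRL).
#' Built in code so fixtures need no downloads.
#'
#' @return named list of `ComponentDefinition` objects.
#' @export
builtin_components <- function() {
  defs <- list(build_ala(), build_gly(),
               build_thiol_serine("CYS", "S", 1.81),
               build_thiol_serine("SER", "O", 1.41),
               build_hoh(), build_act(), build_eth(), build_trl(),
               build_lg1(), build_ket())
  stats::setNames(defs, vapply(defs, `[[`, "", "comp_id"))
}

#' Write a component dictionary as CCD-style CIF
#'
#' @param dict named list of `ComponentDefinition`s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_component_dictionary <- function(dict, path) {
  at <- do.call(rbind, lapply(dict, function(d) data.frame(
    comp_id = d$comp_id, atom_id = d$atoms$name,
    type_symbol = d$atoms$element, charge = d$atoms$charge,
    pdbx_leaving_atom_flag = ifelse(d$atoms$is_leaving, "Y", "N"),
    pdbx_model_Cartn_x_ideal = ifelse(is.na(d$atoms$ix), NA,
                                      sprintf("%.4f", d$atoms$ix)),
    pdbx_model_Cartn_y_ideal = ifelse(is.na(d$atoms$iy), NA,
                                      sprintf("%.4f", d$atoms$iy)),
    pdbx_model_Cartn_z_ideal = ifelse(is.na(d$atoms$iz), NA,
                                      sprintf("%.4f", d$atoms$iz)),
    stringsAsFactors = FALSE)))
  omap <- c(single = "SING", double = "DOUB", triple = "TRIP",
            aromatic = "AROM")
  bd <- do.call(rbind, lapply(dict, function(d) if (nrow(d$bonds)) data.frame(
    comp_id = d$comp_id, atom_id_1 = d$bonds$a, atom_id_2 = d$bonds$b,
    value_order = unname(omap[d$bonds$order]),
    pdbx_aromatic_flag = ifelse(d$bonds$aromatic, "Y", "N"),
    stringsAsFactors = FALSE) else NULL))
  write_cif_categories(list(chem_comp_atom = at, chem_comp_bond = bd), path,
                       block = "components")
}

ONE_TO_THREE <- c(A = "ALA", G = "GLY", C = "CYS", S = "SER")

#' Build a toy peptide structure
#'
#' Heavy-atom peptide built by the internal-coordinate backbone builder;
#' side chains and carbonyl oxygens are placed by superposing each
#' component's ideal coordinates onto the backbone (N, CA, C) frame.
#' Residues at `d_positions` are mirrored locally through the (N, CA, C)
#' plane at CA, so their chiral sign is opposite the L form while the
#' backbone is untouched. The C-terminal residue keeps its OXT; internal
#' residues carry none (a clean, polymerized chain). Intra-component and
#' backbone bonds are attached.
#'
#' @param sequence one-letter string over A, G, C, S.
#' @param d_positions integer positions built as D-residues.
#' @param torsions optional per-residue data.frame (phi, psi, omega) for the
#'   builder; default extended.
#' @param seed integer stored in the state's `rng_seed`.
#' @param chain_id chain identifier.
#' @return list with `state` (a `PipelineState`) and `dict` (the component
#'   dictionary used).
#' @export
make_toy_peptide <- function(sequence, d_positions = integer(),
                             torsions = NULL, seed = 1L, chain_id = "A") {
  codes <- strsplit(sequence, "")[[1]]
  if (!all(codes %in% names(ONE_TO_THREE)))
    stop("unknown residue code(s): ",
         paste(setdiff(codes, names(ONE_TO_THREE)), collapse = ", "))
  dict <- builtin_components()
  n <- length(codes)
  bb <- place_chain_internal(ideal_geometry(), n, place_o = FALSE,
                             torsions = torsions)
  rows <- list()
  for (i in seq_len(n)) {
    comp <- ONE_TO_THREE[[codes[i]]]
    def <- dict[[comp]]
    frame_tab <- bb[bb$res == i, , drop = FALSE]
    tgt <- as.matrix(frame_tab[match(c("N", "CA", "C"), frame_tab$atom_name),
                               c("x", "y", "z")])
    src_names <- c("N", "CA", "C")
    src <- as.matrix(def$atoms[match(src_names, def$atoms$name),
                               c("ix", "iy", "iz")])
    fit <- kabsch_transform(src, tgt)
    heavy <- def$atoms[!(def$atoms$element %in% c("H", "D")), , drop = FALSE]
    if (i < n) heavy <- heavy[!heavy$is_leaving, , drop = FALSE]
    xyz <- sweep(as.matrix(heavy[, c("ix", "iy", "iz")]) %*% fit$R, 2,
                 fit$t, "+")
    if (i %in% d_positions) {
      # local mirror at CA through the backbone plane
      nrm <- kabsch_plane_normal(tgt)
      side <- !(heavy$name %in% c("N", "CA", "C", "O", "OXT"))
      ca <- tgt[2, ]
      for (k in which(side)) {
        v <- xyz[k, ] - ca
        xyz[k, ] <- ca + v - 2 * sum(v * nrm) * nrm
      }
    }
    rows[[i]] <- data.frame(
      atom_uid = NA_integer_, chain_id = chain_id, entity_id = 1L,
      res_index = i, comp_id = comp, atom_name = heavy$name,
      element = heavy$element, altloc = "", occupancy = 1,
      formal_charge = heavy$charge, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      is_resolved = TRUE, stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  atoms$atom_uid <- seq_len(nrow(atoms))
  st <- pipeline_state(atom_table(atoms), rng_seed = seed)
  st <- attach_intra_component_bonds(st, dict)
  list(state = st, dict = dict)
}

kabsch_plane_normal <- function(tgt) {
  v1 <- tgt[1, ] - tgt[2, ]; v2 <- tgt[3, ] - tgt[2, ]
  nrm <- c(v1[2] * v2[3] - v1[3] * v2[2], v1[3] * v2[1] - v1[1] * v2[3],
           v1[1] * v2[2] - v1[2] * v2[1])
  nrm / sqrt(sum(nrm^2))
}

PATHOLOGICAL_CASES <- c("altloc", "leaving_group", "covalent_ligand",
                        "bond_order", "symmetry_ligand", "unresolved_region",
                        "miscounted_charge")

#' Generate a pathological fixture pair
#'
#' Each case is a minimal structure in which exactly one sanitization rule
#' must fire, written as a structure CIF plus component CIF plus a
#' machine-readable expectation (JSON) describing which atoms change.
#'
#' @param case one of `r paste(PATHOLOGICAL_CASES, collapse = ", ")`.
#' @param dir output directory (created if needed).
#' @param seed integer seed recorded in the files.
#' @return list with `structure` (CIF path), `components` (CIF path),
#'   `expectation` (JSON path) and `state` (the in-memory state).
#' @export
make_pathological_cif <- function(case, dir = tempfile("fixture"), seed = 1L) {
  if (!case %in% PATHOLOGICAL_CASES)
    stop("unknown case '", case, "'; known: ",
         paste(PATHOLOGICAL_CASES, collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dict <- builtin_components()
  expectation <- list(case = case, seed = seed)
  if (case == "altloc") {
    tp <- make_toy_peptide("AA", seed = seed)
    st <- tp$state
    a <- st$table$atoms
    cb <- which(a$res_index == 1 & a$atom_name == "CB")
    st$table$atoms$altloc[cb] <- "A"
    st$table$atoms$occupancy[cb] <- 0.6
    alt <- a[cb, ]
    alt$atom_uid <- next_uids(st$table, 1L)
    alt$altloc <- "B"; alt$occupancy <- 0.4
    alt$x <- alt$x + 0.8
    st$table$atoms <- rbind(st$table$atoms, alt)
    expectation$rule <- "resolve_altlocs"
    expectation$kept <- list(res_index = 1, atom_name = "CB", altloc = "A")
    expectation$deleted <- list(list(res_index = 1, atom_name = "CB",
                                     altloc = "B"))
  } else if (case == "leaving_group") {
    tp <- make_toy_peptide("AA", seed = seed)
    st <- tp$state
    # deposit residue 1 with its (spurious) OXT still present
    def <- dict$ALA
    a <- st$table$atoms
    frame <- a[a$res_index == 1 & a$atom_name %in% c("N", "CA", "C"), ]
    src <- as.matrix(def$atoms[match(c("N", "CA", "C"), def$atoms$name),
                               c("ix", "iy", "iz")])
    fit <- kabsch_transform(src, as.matrix(frame[, c("x", "y", "z")]))
    ox <- as.numeric(as.matrix(def$atoms[def$atoms$name == "OXT",
                                         c("ix", "iy", "iz")]) %*% fit$R + fit$t)
    uid <- next_uids(st$table, 1L)
    st$table$atoms <- rbind(st$table$atoms, data.frame(
      atom_uid = uid, chain_id = "A", entity_id = 1L, res_index = 1L,
      comp_id = "ALA", atom_name = "OXT", element = "O", altloc = "",
      occupancy = 1, formal_charge = 0L, x = ox[1], y = ox[2], z = ox[3],
      is_resolved = TRUE, stringsAsFactors = FALSE))
    st <- attach_intra_component_bonds(st, dict)
    expectation$rule <- "remove_leaving_groups"
    expectation$deleted <- list(list(res_index = 1, atom_name = "OXT"))
    expectation$kept <- list(res_index = 2, atom_name = "OXT")
  } else if (case %in% c("covalent_ligand", "bond_order")) {
    tp <- make_toy_peptide("ACA", seed = seed)
    st <- tp$state
    a <- st$table$atoms
    sg <- a[a$atom_name == "SG", ]
    lig_comp <- if (case == "covalent_ligand") "LG1" else "KET"
    def <- dict[[lig_comp]]
    keep <- if (case == "covalent_ligand")
      def$atoms$name %in% c("C1", "C2", "O2", "H1") else
        !(def$atoms$element %in% c("H", "D"))
    lat <- def$atoms[keep, , drop = FALSE]
    # place the ligand so its link atom C1 sits 1.81 A from SG
    dir_out <- c(sg$x, sg$y, sg$z) -
      as.numeric(a[a$atom_name == "CB" & a$res_index == 2, c("x", "y", "z")])
    dir_out <- dir_out / sqrt(sum(dir_out^2))
    c1_target <- c(sg$x, sg$y, sg$z) + 1.81 * dir_out
    shift <- c1_target - as.numeric(lat[lat$name == "C1", c("ix", "iy", "iz")])
    uids <- next_uids(st$table, nrow(lat))
    st$table$atoms <- rbind(st$table$atoms, data.frame(
      atom_uid = uids, chain_id = "B", entity_id = 2L, res_index = 1L,
      comp_id = lig_comp, atom_name = lat$name, element = lat$element,
      altloc = "", occupancy = 1, formal_charge = lat$charge,
      x = lat$ix + shift[1], y = lat$iy + shift[2], z = lat$iz + shift[3],
      is_resolved = TRUE, stringsAsFactors = FALSE))
    st <- attach_intra_component_bonds(st, dict)
    st$extras$struct_conn <- data.frame(
      conn_type = "covale", chain1 = "A", res1 = 2L, comp1 = "CYS",
      atom1 = "SG", chain2 = "B", res2 = 1L, comp2 = lig_comp, atom2 = "C1",
      order = "single", stringsAsFactors = FALSE)
    # materialize the link so the written CIF carries a struct_conn row
    st <- detect_covalent_links(st)
    if (case == "covalent_ligand") {
      expectation$rule <- "remove_leaving_groups"
      expectation$deleted <- list(list(chain_id = "B", atom_name = "H1"))
      expectation$heavy_atoms_conserved <- TRUE
    } else {
      expectation$rule <- "correct_bond_order_after_addition"
      expectation$demoted <- list(a = "C1", b = "O1", from = "double",
                                  to = "single")
    }
  } else if (case == "symmetry_ligand") {
    tp <- make_toy_peptide("AAA", seed = seed)
    st <- tp$state
    act <- dict$ACT$atoms
    act <- act[!(act$element %in% c("H", "D")), ]
    base <- c(12, 0, 0)
    for (copy in 1:2) {
      uids <- next_uids(st$table, nrow(act))
      jitter <- if (copy == 2) c(0.3, 0.2, -0.1) else c(0, 0, 0)
      st$table$atoms <- rbind(st$table$atoms, data.frame(
        atom_uid = uids, chain_id = "L", entity_id = 2L, res_index = copy,
        comp_id = "ACT", atom_name = act$name, element = act$element,
        altloc = "", occupancy = 0.5, formal_charge = act$charge,
        x = act$ix + base[1] + jitter[1], y = act$iy + base[2] + jitter[2],
        z = act$iz + base[3] + jitter[3],
        is_resolved = TRUE, stringsAsFactors = FALSE))
    }
    st <- attach_intra_component_bonds(st, dict)
    expectation$rule <- "deduplicate_symmetry_ligands"
    expectation$kept <- list(chain_id = "L", res_index = 1)
    expectation$deleted <- list(list(chain_id = "L", res_index = 2))
  } else if (case == "unresolved_region") {
    tp <- make_toy_peptide("AAAAA", seed = seed)
    st <- tp$state
    # residues 4-5 stay in entity_poly_seq but get no atom_site rows
    unres <- st$table$atoms$res_index %in% 4:5
    st$table$atoms$is_resolved[unres] <- FALSE
    st$table$atoms$x[unres] <- NA_real_
    st$table$atoms$y[unres] <- NA_real_
    st$table$atoms$z[unres] <- NA_real_
    st$table$atoms$occupancy[unres] <- 0
    expectation$rule <- "ingest_unresolved"
    expectation$unresolved_residues <- list(4, 5)
  } else if (case == "miscounted_charge") {
    tp <- make_toy_peptide("AA", seed = seed)
    st <- tp$state
    act <- dict$ACT$atoms
    act <- act[!(act$element %in% c("H", "D")), ]
    uids <- next_uids(st$table, nrow(act))
    st$table$atoms <- rbind(st$table$atoms, data.frame(
      atom_uid = uids, chain_id = "L", entity_id = 2L, res_index = 1L,
      comp_id = "ACT", atom_name = act$name, element = act$element,
      altloc = "", occupancy = 1, formal_charge = 0L,  # deposited wrong
      x = act$ix + 12, y = act$iy, z = act$iz,
      is_resolved = TRUE, stringsAsFactors = FALSE))
    st <- attach_intra_component_bonds(st, dict)
    expectation$rule <- "assign_formal_charges"
    expectation$charges <- list(list(chain_id = "L", atom_name = "OXT",
                                     formal_charge = -1))
  }
  paths <- list(structure = file.path(dir, paste0(case, ".cif")),
                components = file.path(dir, "components.cif"),
                expectation = file.path(dir, paste0(case, "_expected.json")))
  write_mmcif(st, paths$structure)
  write_component_dictionary(dict, paths$components)
  jsonlite::write_json(expectation, paths$expectation, auto_unbox = TRUE,
                       pretty = TRUE)
  c(paths, list(state = st))
}

#' Deliberately mis-annotated acetate twin
#'
#' The built-in acetate with its carboxylate oxygen wrongly annotated +1
#' instead of -1 — the kind of charge error sanitization exists to fix.
#' Its minimized conformer energy exceeds the correctly annotated
#' version's, since the force field parameterizes the molecule from the
#' annotated graph alone.
#'
#' @return a `ComponentDefinition`.
#' @export
mischarged_act <- function() {
  bad <- build_act()
  bad$atoms$charge[bad$atoms$name == "OXT"] <- 1L
  bad
}

#' Seeded isotropic coordinate noise
#'
#' Adds Gaussian noise with standard deviation `sigma` per axis to the
#' resolved coordinates; `sigma = 0` is the identity. Used to manufacture
#' graded-accuracy predictions for metric tests.
#'
#' @param state a `PipelineState`.
#' @param sigma noise level in angstroms (>= 0).
#' @param seed integer seed.
#' @return the perturbed state.
#' @export
perturb_structure <- function(state, sigma, seed = 1L) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(state)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  a <- state$table$atoms
  idx <- which(a$is_resolved & is.finite(a$x))
  noise <- matrix(stats::rnorm(3 * length(idx), sd = sigma), ncol = 3)
  state$table$atoms$x[idx] <- a$x[idx] + noise[, 1]
  state$table$atoms$y[idx] <- a$y[idx] + noise[, 2]
  state$table$atoms$z[idx] <- a$z[idx] + noise[, 3]
  state
}
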