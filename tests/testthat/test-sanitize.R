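test_that("altloc resolution keeps the highest-occupancy copy", {
  mk_altloc <- function(occA, occB) {
    tp <- make_toy_peptide("AA")
    st <- tp$state
    a <- st$table$atoms
    cb <- which(a$res_index == 1 & a$atom_name == "CB")
    st$table$atoms$altloc[cb] <- "A"
    st$table$atoms$occupancy[cb] <- occA
    alt <- a[cb, ]
    alt$atom_uid <- next_uids <- max(a$atom_uid) + 1L
    alt$altloc <- "B"; alt$occupancy <- occB; alt$x <- alt$x + 0.7
    st$table$atoms <- rbind(st$table$atoms, alt)
    st
  }
  # argmax rule
  st <- mk_altloc(0.6, 0.4)
  out <- resolve_altlocs(st)
  cb <- out$table$atoms[out$table$atoms$atom_name == "CB" &
                          out$table$atoms$res_index == 1, ]
  expect_equal(nrow(cb), 1L)
  expect_equal(cb$occupancy, 0.6)
  expect_equal(cb$altloc, "")
  # tie goes to the lexicographically smallest altloc
  st2 <- mk_altloc(0.5, 0.5)
  out2 <- resolve_altlocs(st2)
  cb2 <- out2$table$atoms[out2$table$atoms$atom_name == "CB" &
                            out2$table$atoms$res_index == 1, ]
  expect_equal(cb2$x, st2$table$atoms$x[st2$table$atoms$altloc == "A"])
  # no altlocs: identity; second application: identity (idempotent)
  tp <- make_toy_peptide("AA")
  expect_identical(resolve_altlocs(tp$state)$table$atoms, tp$state$table$atoms)
  expect_identical(resolve_altlocs(out)$table$atoms, out$table$atoms)
})

test_that("leaving groups are removed only at bonded linkage sites", {
  dict <- builtin_components()
  # dipeptide deposited with a spurious OXT on the linked residue 1
  fx <- make_pathological_cif("leaving_group", dir = withr::local_tempdir())
  st <- read_mmcif(fx$structure, components = dict)
  st <- attach_intra_component_bonds(st, dict)
  out <- remove_leaving_groups(st, dict)
  a <- out$table$atoms
  expect_false(any(a$res_index == 1 & a$atom_name == "OXT"))
  expect_true(any(a$res_index == 2 & a$atom_name == "OXT"))  # terminal kept
  # idempotent
  expect_identical(remove_leaving_groups(out, dict)$table$atoms, a)
  # a free amino-acid ligand with no links loses nothing
  free <- component_state("ALA")
  free$table$atoms <- free$table$atoms  # single residue, no inter bonds
  out2 <- remove_leaving_groups(free, dict)
  expect_equal(nrow(out2$table$atoms), nrow(free$table$atoms))
})

test_that("covalently bound ligand loses its leaving hydrogen, heavy atoms conserved", {
  fx <- make_pathological_cif("covalent_ligand", dir = withr::local_tempdir())
  dict <- read_component_dictionary(fx$components)
  st <- read_mmcif(fx$structure, components = dict)
  st <- attach_intra_component_bonds(st, dict)
  st <- detect_covalent_links(st)
  out <- remove_leaving_groups(st, dict)
  expect_false("H1" %in% out$table$atoms$atom_name)
  heavy <- function(s) sum(!(s$table$atoms$element %in% c("H", "D")))
  expect_equal(heavy(out), heavy(st))
})

test_that("struct_conn records become bonds; metalc stays an annotation", {
  tp <- make_toy_peptide("ACCA")
  st <- tp$state
  st$extras$struct_conn <- data.frame(
    conn_type = c("disulf", "metalc", "covale"),
    chain1 = "A", res1 = c(2L, 2L, 99L), comp1 = "CYS",
    atom1 = c("SG", "SG", "SG"),
    chain2 = "A", res2 = c(3L, 3L, 3L), comp2 = "CYS",
    atom2 = c("SG", "SG", "SG"), order = NA_character_,
    stringsAsFactors = FALSE)
  expect_warning(out <- detect_covalent_links(st), "unresolvable")
  b <- out$table$bonds
  a <- out$table$atoms
  sg <- a$atom_uid[a$atom_name == "SG"]
  ss <- b[b$atom_a %in% sg & b$atom_b %in% sg, ]
  expect_equal(nrow(ss), 1L)
  expect_equal(ss$provenance, "struct_conn")
  expect_equal(nrow(out$extras$metal_contacts), 1L)
})

test_that("distance inference finds the ligand-SG link only when enabled", {
  tp <- make_toy_peptide("AC")
  st <- tp$state
  a <- st$table$atoms
  sg <- a[a$atom_name == "SG", ]
  # ligand carbon 1.45 A from SG: within 0.76 + 1.05 + 0.4 = 2.21 A
  uid <- max(a$atom_uid) + 1L
  st$table$atoms <- rbind(a, data.frame(
    atom_uid = uid, chain_id = "L", entity_id = 2L, res_index = 1L,
    comp_id = "KET", atom_name = "C2", element = "C", altloc = "",
    occupancy = 1, formal_charge = 0L, x = sg$x + 1.45, y = sg$y, z = sg$z,
    is_resolved = TRUE, stringsAsFactors = FALSE))
  # ligand-polymer bonds only: backbone peptide links carry their own
  # (sequence-derived) inferred provenance and are not distance inference
  lig_pol_bonds <- function(s) {
    b <- s$table$bonds
    aa <- s$table$atoms
    ca <- aa$comp_id[match(b$atom_a, aa$atom_uid)]
    cb <- aa$comp_id[match(b$atom_b, aa$atom_uid)]
    b[xor(ca == "KET", cb == "KET"), , drop = FALSE]
  }
  off <- detect_covalent_links(st, infer_by_distance = FALSE)
  expect_equal(nrow(lig_pol_bonds(off)), 0L)
  on <- detect_covalent_links(st, infer_by_distance = TRUE)
  inf <- lig_pol_bonds(on)
  expect_equal(nrow(inf), 1L)
  expect_equal(inf$provenance, "inferred")
  expect_setequal(c(inf$atom_a, inf$atom_b), c(sg$atom_uid, uid))
})

test_that("bond order is demoted after nucleophilic addition", {
  fx <- make_pathological_cif("bond_order", dir = withr::local_tempdir())
  dict <- read_component_dictionary(fx$components)
  st <- read_mmcif(fx$structure, components = dict)
  st <- attach_intra_component_bonds(st, dict)
  st <- detect_covalent_links(st)
  out <- correct_bond_order_after_addition(st, dict)
  a <- out$table$atoms; b <- out$table$bonds
  c1 <- a$atom_uid[a$atom_name == "C1"]; o1 <- a$atom_uid[a$atom_name == "O1"]
  co <- b[(b$atom_a == c1 & b$atom_b == o1) | (b$atom_a == o1 & b$atom_b == c1), ]
  expect_equal(co$order, "single")
  # sp3 atom with free valence is untouched
  c4 <- a$atom_uid[a$atom_name == "C4"]
  expect_equal(sum(b$atom_a == c4 | b$atom_b == c4),
               sum(st$table$bonds$atom_a == c4 | st$table$bonds$atom_b == c4))
  # quaternary carbon with no double bond: error naming the atom
  stq <- point_state(rbind(c(0, 0, 0), c(1.5, 0, 0), c(-1.5, 0, 0),
                           c(0, 1.5, 0), c(0, -1.5, 0), c(0, 0, 1.5)))
  stq$table$atoms$atom_name <- paste0("C", 1:6)
  stq$table$atoms$res_index <- c(1L, 1L, 1L, 1L, 1L, 2L)
  stq$table$bonds <- data.frame(
    atom_a = 1L, atom_b = 2:6, order = "single",
    provenance = c(rep("intra_component", 4), "struct_conn"),
    stringsAsFactors = FALSE)
  expect_error(correct_bond_order_after_addition(stq), "no double bond")
})

test_that("formal charges follow valence bookkeeping", {
  fx <- make_pathological_cif("miscounted_charge", dir = withr::local_tempdir())
  dict <- read_component_dictionary(fx$components)
  st <- read_mmcif(fx$structure, components = dict)
  st <- attach_intra_component_bonds(st, dict)
  out <- assign_formal_charges(st, dict)
  a <- out$table$atoms
  # carboxylate O with one single bond and no H: -1
  expect_equal(a$formal_charge[a$comp_id == "ACT" & a$atom_name == "OXT"], -1L)
  # carbonyl O (double bond): 0; carbons: 0
  expect_equal(a$formal_charge[a$comp_id == "ACT" & a$atom_name == "O"], 0L)
  expect_true(all(a$formal_charge[a$element == "C"] == 0L))
  # nitrogen with four single bonds: +1
  stn <- point_state(rbind(c(0, 0, 0), c(1.5, 0, 0), c(-1.5, 0, 0),
                           c(0, 1.5, 0), c(0, -1.5, 0)), comp = "XXX")
  stn$table$atoms$element <- c("N", "C", "C", "C", "C")
  stn$table$atoms$atom_name <- c("N", "C1", "C2", "C3", "C4")
  stn$table$atoms$res_index <- 1L
  stn$table$bonds <- data.frame(atom_a = 1L, atom_b = 2:5, order = "single",
                                provenance = "intra_component",
                                stringsAsFactors = FALSE)
  outn <- assign_formal_charges(stn)
  expect_equal(outn$table$atoms$formal_charge[1], 1L)
  # water: 0 (explicit H)
  hoh <- component_state("HOH", heavy_only = FALSE)
  expect_equal(assign_formal_charges(hoh, dict)$table$atoms$formal_charge,
               c(0L, 0L, 0L))
  # element missing from the table errors by name
  stx <- stn
  stx$table$atoms$element[1] <- "XE"
  expect_error(assign_formal_charges(stx), "XE")
})

test_that("total charge matches component definitions on clean fixtures", {
  dict <- builtin_components()
  act <- component_state("ACT", heavy_only = FALSE)
  out <- assign_formal_charges(act, dict)
  expect_equal(sum(out$table$atoms$formal_charge),
               sum(dict$ACT$atoms$charge))
  tp <- make_toy_peptide("AGA")
  outp <- assign_formal_charges(tp$state, dict)
  expect_equal(sum(outp$table$atoms$formal_charge), 0L)
})

test_that("symmetry-center ligand copies deduplicate by the occupancy rule", {
  fx <- make_pathological_cif("symmetry_ligand", dir = withr::local_tempdir())
  dict <- read_component_dictionary(fx$components)
  st <- read_mmcif(fx$structure, components = dict)
  out <- deduplicate_symmetry_ligands(st)
  lig <- out$table$atoms[out$table$atoms$comp_id == "ACT", ]
  expect_equal(unique(lig$res_index), 1L)
  # idempotent
  expect_identical(deduplicate_symmetry_ligands(out)$table$atoms,
                   out$table$atoms)
  # copies far apart both survive
  far <- st
  sel <- far$table$atoms$comp_id == "ACT" & far$table$atoms$res_index == 2
  far$table$atoms$x[sel] <- far$table$atoms$x[sel] + 20
  out2 <- deduplicate_symmetry_ligands(far)
  expect_setequal(unique(out2$table$atoms$res_index[
    out2$table$atoms$comp_id == "ACT"]), 1:2)
  # a full-occupancy single ligand is untouched
  one <- component_state("ACT")
  expect_identical(deduplicate_symmetry_ligands(one)$table$atoms,
                   one$table$atoms)
})

test_that("missing intra-residue atoms are imputed by rigid superposition", {
  dict <- builtin_components()
  tp <- make_toy_peptide("AAA")
  st <- tp$state
  a <- st$table$atoms
  cb2 <- a$atom_uid[a$res_index == 2 & a$atom_name == "CB"]
  st <- delete_atoms(st, cb2)
  out <- impute_missing_intra_residue(st, dict)
  a2 <- out$table$atoms
  newcb <- a2[a2$res_index == 2 & a2$atom_name == "CB", ]
  expect_equal(nrow(newcb), 1L)
  expect_false(newcb$is_resolved)
  ca2 <- a2[a2$res_index == 2 & a2$atom_name == "CA", ]
  d <- sqrt((newcb$x - ca2$x)^2 + (newcb$y - ca2$y)^2 + (newcb$z - ca2$z)^2)
  ideal <- dict$ALA$atoms
  dref <- sqrt(sum((as.numeric(ideal[ideal$name == "CB", c("ix", "iy", "iz")]) -
                      as.numeric(ideal[ideal$name == "CA", c("ix", "iy", "iz")]))^2))
  expect_lt(abs(d - dref), 0.05)
  expect_true(newcb$atom_uid %in% out$extras$imputed)
  # fully resolved residue: identity
  out2 <- impute_missing_intra_residue(tp$state, dict)
  expect_identical(out2$table$atoms, tp$state$table$atoms)
  # residue with <3 resolved atoms is reported, unchanged
  st3 <- tp$state
  drop <- st3$table$atoms$atom_uid[st3$table$atoms$res_index == 2 &
                                     !(st3$table$atoms$atom_name %in% c("N", "CA"))]
  st3 <- delete_atoms(st3, drop)
  out3 <- impute_missing_intra_residue(st3, dict)
  expect_equal(nrow(out3$table$atoms[out3$table$atoms$res_index == 2, ]), 2L)
  expect_true(any(grepl("skipped", unlist(out3$log))))
})

test_that("every pathological fixture fires exactly its rule through the pipeline", {
  for (case in structforge:::PATHOLOGICAL_CASES) {
    fx <- make_pathological_cif(case, dir = withr::local_tempdir(), seed = 1)
    expected <- jsonlite::read_json(fx$expectation)
    dict <- read_component_dictionary(fx$components)
    st <- read_mmcif(fx$structure, components = dict)
    out <- apply_pipeline(sanitize_pipeline(components = fx$components), st)
    a <- out$table$atoms
    if (!is.null(expected$deleted)) {
      for (d in expected$deleted) {
        sel <- rep(TRUE, nrow(a))
        if (!is.null(d$res_index)) sel <- sel & a$res_index == d$res_index
        if (!is.null(d$chain_id)) sel <- sel & a$chain_id == d$chain_id
        if (!is.null(d$atom_name)) sel <- sel & a$atom_name == d$atom_name
        if (!is.null(d$altloc)) sel <- sel & FALSE  # altloc ids cleared on keep
        expect_equal(sum(sel), 0, info = paste(case, "deleted"))
      }
    }
    if (!is.null(expected$charges)) {
      for (cg in expected$charges) {
        sel <- a$chain_id == cg$chain_id & a$atom_name == cg$atom_name
        expect_equal(a$formal_charge[sel], as.integer(cg$formal_charge),
                     info = case)
      }
    }
    if (identical(case, "unresolved_region")) {
      expect_setequal(unique(a$res_index[!a$is_resolved]),
                      unlist(expected$unresolved_residues))
    }
    if (identical(case, "bond_order")) {
      b <- out$table$bonds
      c1 <- a$atom_uid[a$atom_name == expected$demoted$a]
      o1 <- a$atom_uid[a$atom_name == expected$demoted$b]
      co <- b[(b$atom_a %in% c1 & b$atom_b %in% o1) |
                (b$atom_a %in% o1 & b$atom_b %in% c1), ]
      expect_equal(co$order, expected$demoted$to, info = case)
    }
    # sanitization is idempotent end-to-end: writing and re-sanitizing
    # changes nothing further
    f2 <- file.path(withr::local_tempdir(), "pass2.cif")
    write_mmcif(out, f2)
    st2 <- read_mmcif(f2, components = dict)
    out2 <- apply_pipeline(sanitize_pipeline(components = fx$components), st2)
    expect_equal(nrow(out2$table$atoms), nrow(out$table$atoms), info = case)
  }
})
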