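# Sanitization transforms: altloc resolution, leaving-group removal,
# covalent-link detection, bond-order correction after nucleophilic addition,
# formal-charge assignment, symmetry-ligand deduplication, and intra-residue
# coordinate imputation. Each is a PipelineState -> PipelineState transform;
# deletions are logged per rule, and every transform is idempotent.

#' Standard valence table
#'
#' Allowed bonded-electron-pair counts per element, used by charge assignment
#' and bond-order correction. Hypervalent elements list every allowed count
#' (e.g. S: 2, 4, 6).
#'
#' @return named list element -> integer vector of allowed valences.
#' @export
default_valence_table <- function() {
  list(H = 1L, D = 1L, C = 4L, N = 3L, O = 2L, S = c(2L, 4L, 6L),
       P = c(3L, 5L), F = 1L, CL = 1L, BR = 1L, I = 1L, SE = c(2L, 4L, 6L),
       B = 3L, SI = 4L)
}

#' Single-bond covalent radii (angstroms)
#'
#' Standard published single-bond covalent radii used for distance-based
#' covalent-link inference.
#'
#' @return named numeric vector, element -> radius.
#' @export
covalent_radii <- function() {
  c(H = 0.31, D = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57, P = 1.07,
    S = 1.05, CL = 1.02, SE = 1.20, BR = 1.20, I = 1.39, B = 0.84, SI = 1.11,
    NA_ = 1.66, MG = 1.41, K = 2.03, CA = 1.76, MN = 1.39, FE = 1.32,
    CO = 1.26, NI = 1.24, CU = 1.32, ZN = 1.22)
}

bond_order_value <- function(order) {
  c(single = 1, double = 2, triple = 3, aromatic = 1.5)[order]
}

# sum of bond orders at each atom; aromatic counts 1.5
order_sums <- function(table) {
  a <- table$atoms; b <- table$bonds
  s <- stats::setNames(numeric(nrow(a)), a$atom_uid)
  if (nrow(b)) {
    v <- bond_order_value(b$order)
    for (i in seq_len(nrow(b))) {
      s[as.character(b$atom_a[i])] <- s[as.character(b$atom_a[i])] + v[i]
      s[as.character(b$atom_b[i])] <- s[as.character(b$atom_b[i])] + v[i]
    }
  }
  s
}

# implicit hydrogen count per atom: hydrogens bonded in the component
# definition but absent from the table for that residue. Leaving-flagged
# hydrogens are not counted at atoms that already participate in an
# inter-residue bond — they depart with polymerization/linkage.
implicit_h_counts <- function(table, dict) {
  a <- table$atoms
  b <- table$bonds
  out <- stats::setNames(integer(nrow(a)), a$atom_uid)
  linked <- integer()
  if (nrow(b)) {
    ia <- match(b$atom_a, a$atom_uid); ib <- match(b$atom_b, a$atom_uid)
    inter <- residue_key(a[ia, ]) != residue_key(a[ib, ])
    linked <- unique(c(b$atom_a[inter], b$atom_b[inter]))
  }
  for (key in unique(residue_key(a))) {
    rows <- a[residue_key(a) == key, , drop = FALSE]
    def <- dict[[rows$comp_id[1]]]
    if (is.null(def)) next
    hset <- toupper(def$atoms$element) %in% c("H", "D")
    h_names <- def$atoms$name[hset]
    h_leaving <- def$atoms$name[hset & def$atoms$is_leaving]
    for (i in seq_len(nrow(rows))) {
      nb <- c(def$bonds$b[def$bonds$a == rows$atom_name[i]],
              def$bonds$a[def$bonds$b == rows$atom_name[i]])
      hnb <- setdiff(intersect(nb, h_names), rows$atom_name)
      if (rows$atom_uid[i] %in% linked) hnb <- setdiff(hnb, h_leaving)
      out[as.character(rows$atom_uid[i])] <- length(hnb)
    }
  }
  out
}

#' Resolve alternate locations
#'
#' For each (chain, res_index, atom_name) modelled in more than one altloc,
#' keeps exactly the copy with the highest occupancy (tie: lexicographically
#' smallest altloc id), clears its altloc and preserves its occupancy. Input
#' without altlocs is returned unchanged; the transform is idempotent.
#'
#' @param state a `PipelineState`.
#' @return the updated state.
#' @export
resolve_altlocs <- function(state) {
  a <- state$table$atoms
  key <- paste(a$chain_id, a$res_index, a$atom_name, sep = "\r")
  drop <- integer()
  cleared <- integer()
  for (k in unique(key[a$altloc != ""])) {
    grp <- which(key == k)
    if (length(grp) == 1L) { cleared <- c(cleared, grp); next }
    ord <- order(-a$occupancy[grp], a$altloc[grp])
    keep <- grp[ord[1]]
    drop <- c(drop, setdiff(grp, keep))
    cleared <- c(cleared, keep)
  }
  if (length(drop)) {
    state <- delete_atoms(state, a$atom_uid[drop])
    state$log <- c(state$log, list(sprintf(
      "resolve_altlocs: removed %d lower-occupancy altloc copies", length(drop))))
  }
  if (length(cleared)) {
    idx <- match(a$atom_uid[cleared], state$table$atoms$atom_uid)
    state$table$atoms$altloc[idx[!is.na(idx)]] <- ""
  }
  validate_atom_table(state$table)
  state
}

# leaving atoms attached to a linkage-site atom: leaving-flagged atoms bonded
# (in the component definition) to the site, expanded through connected
# leaving atoms, plus hydrogens bonded to any of them
leaving_set_at <- function(def, site_atom) {
  at <- def$atoms; bd <- def$bonds
  nbrs <- function(nm) c(bd$b[bd$a == nm], bd$a[bd$b == nm])
  leaving <- at$name[at$is_leaving]
  hydro <- at$name[toupper(at$element) %in% c("H", "D")]
  front <- intersect(nbrs(site_atom), leaving)
  seen <- character()
  while (length(front)) {
    seen <- union(seen, front)
    front <- setdiff(intersect(unlist(lapply(front, nbrs)), leaving), seen)
  }
  union(seen, intersect(unlist(lapply(seen, nbrs)), hydro))
}

#' Remove leaving groups at covalent linkage sites
#'
#' For every atom participating in an inter-residue covalent bond (polymer
#' backbone link, struct_conn record, or inferred link), deletes the
#' leaving-flagged atoms of its component that are attached to that linkage
#' site, together with their hydrogens. Leaving atoms at non-linked sites are
#' retained, mirroring CCD semantics: a terminal residue keeps its OXT.
#'
#' @param state a `PipelineState` with intra-component and link bonds present.
#' @param dict component dictionary.
#' @return the updated state.
#' @export
remove_leaving_groups <- function(state, dict) {
  a <- state$table$atoms; b <- state$table$bonds
  if (!nrow(b)) return(state)
  ia <- match(b$atom_a, a$atom_uid); ib <- match(b$atom_b, a$atom_uid)
  inter <- residue_key(a[ia, ]) != residue_key(a[ib, ])
  doomed <- integer()
  for (i in which(inter)) {
    for (side in list(ia[i], ib[i])) {
      row <- a[side, ]
      def <- dict[[row$comp_id]]
      if (is.null(def)) stop("no component definition for ", row$comp_id)
      lv <- leaving_set_at(def, row$atom_name)
      if (!length(lv)) next
      here <- a$atom_uid[residue_key(a) == residue_key(row) & a$atom_name %in% lv]
      doomed <- union(doomed, here)
    }
  }
  if (length(doomed)) {
    state <- delete_atoms(state, doomed)
    state$log <- c(state$log, list(sprintf(
      "remove_leaving_groups: deleted %d leaving atoms at linkage sites",
      length(doomed))))
  }
  state
}

#' Turn struct_conn records into bonds; optionally infer covalent links
#'
#' Each `covale`/`disulf` record in `extras$struct_conn` becomes a single
#' bond with provenance `struct_conn`; `metalc` records become annotations in
#' `extras$metal_contacts`, never bonds. Unresolvable partners are skipped
#' with a warning and counted in the log. With `infer_by_distance`, ligand
#' (non-polymer) heavy atoms within the covalent-radius sum plus `slack` of a
#' polymer heavy atom, both with free valence, gain a bond with provenance
#' `inferred` — off by default, since struct_conn is authoritative.
#'
#' @param state a `PipelineState`.
#' @param records optional struct_conn data.frame; defaults to
#'   `state$extras$struct_conn`.
#' @param infer_by_distance logical, default FALSE.
#' @param slack distance slack in angstroms added to the radius sum.
#' @return the updated state.
#' @export
detect_covalent_links <- function(state, records = NULL,
                                  infer_by_distance = FALSE, slack = 0.4) {
  a <- state$table$atoms
  if (is.null(records)) records <- state$extras$struct_conn
  add <- list()
  skipped <- 0L
  if (!is.null(records) && nrow(records)) {
    find_uid <- function(ch, rs, nm) {
      hit <- a$atom_uid[a$chain_id == ch & a$res_index == rs & a$atom_name == nm]
      if (length(hit)) hit[1] else NA_integer_
    }
    for (i in seq_len(nrow(records))) {
      r <- records[i, ]
      u1 <- find_uid(r$chain1, r$res1, r$atom1)
      u2 <- find_uid(r$chain2, r$res2, r$atom2)
      if (is.na(u1) || is.na(u2)) { skipped <- skipped + 1L; next }
      if (identical(r$conn_type, "metalc")) {
        state$extras$metal_contacts <- rbind(
          state$extras$metal_contacts,
          data.frame(atom_a = u1, atom_b = u2, stringsAsFactors = FALSE))
        next
      }
      ord <- if (!is.null(r$order) && !is.na(r$order) &&
                 tolower(r$order) %in% BOND_ORDERS) tolower(r$order) else "single"
      add[[length(add) + 1L]] <- data.frame(
        atom_a = u1, atom_b = u2, order = ord, provenance = "struct_conn",
        stringsAsFactors = FALSE)
    }
    if (skipped) {
      warning(skipped, " struct_conn record(s) with unresolvable partners skipped")
      state$log <- c(state$log, list(sprintf(
        "detect_covalent_links: %d unresolvable records skipped", skipped)))
    }
  }
  if (infer_by_distance) {
    rad <- covalent_radii()
    vt <- default_valence_table()
    osum <- order_sums(state$table)
    heavy <- a$is_resolved & !(a$element %in% c("H", "D"))
    lig <- heavy & !is_polymer_comp(a$comp_id)
    pol <- heavy & is_polymer_comp(a$comp_id)
    free_val <- function(uid, el) {
      v <- vt[[el]]
      if (is.null(v)) return(FALSE)
      osum[as.character(uid)] < max(v)
    }
    for (i in which(lig)) for (j in which(pol)) {
      d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 + (a$z[i] - a$z[j])^2)
      lim <- unname(rad[a$element[i]] + rad[a$element[j]]) + slack
      if (!is.na(lim) && d <= lim &&
          free_val(a$atom_uid[i], a$element[i]) &&
          free_val(a$atom_uid[j], a$element[j])) {
        add[[length(add) + 1L]] <- data.frame(
          atom_a = a$atom_uid[i], atom_b = a$atom_uid[j], order = "single",
          provenance = "inferred", stringsAsFactors = FALSE)
      }
    }
  }
  if (length(add)) {
    nb <- do.call(rbind, add)
    all_b <- rbind(state$table$bonds, nb)
    pk <- paste(pmin(all_b$atom_a, all_b$atom_b), pmax(all_b$atom_a, all_b$atom_b))
    state$table$bonds <- all_b[!duplicated(pk), , drop = FALSE]
    state$log <- c(state$log, list(sprintf(
      "detect_covalent_links: %d link bond(s) attached", nrow(nb))))
  }
  validate_atom_table(state$table)
  state
}

#' Correct bond orders after nucleophilic addition
#'
#' A new covalent link can push an atom over its allowed valence (the classic
#' case: addition to a carbonyl carbon). For each atom whose bond-order sum
#' plus implicit hydrogens exceeds its maximum allowed valence, one double
#' bond at that atom is demoted to single, preferring a C=O partner, then
#' C=N, then any other. Formal charges are left to
#' [assign_formal_charges()], which should run afterwards.
#'
#' @param state a `PipelineState` with bond orders attached.
#' @param dict component dictionary (for implicit hydrogen counts).
#' @param valences valence table, see [default_valence_table()].
#' @return the updated state.
#' @export
correct_bond_order_after_addition <- function(state, dict = list(),
                                              valences = default_valence_table()) {
  a <- state$table$atoms
  osum <- order_sums(state$table)
  ih <- if (length(dict)) implicit_h_counts(state$table, dict) else
    stats::setNames(integer(nrow(a)), a$atom_uid)
  changed <- 0L
  for (i in seq_len(nrow(a))) {
    el <- a$element[i]
    v <- valences[[el]]
    if (is.null(v)) next
    uid <- a$atom_uid[i]
    excess <- osum[as.character(uid)] + ih[as.character(uid)] - max(v)
    if (excess < 1) next
    b <- state$table$bonds
    at_i <- which((b$atom_a == uid | b$atom_b == uid) & b$order == "double")
    if (!length(at_i))
      stop("atom_uid ", uid, " (", el, ") exceeds valence by ", excess,
           " but has no double bond to demote; upstream chemistry problem")
    partner_uid <- ifelse(b$atom_a[at_i] == uid, b$atom_b[at_i], b$atom_a[at_i])
    partner_el <- a$element[match(partner_uid, a$atom_uid)]
    pref <- match(partner_el, c("O", "N"))
    pick <- at_i[order(ifelse(is.na(pref), 3L, pref))][1]
    state$table$bonds$order[pick] <- "single"
    osum <- order_sums(state$table)
    changed <- changed + 1L
  }
  if (changed) state$log <- c(state$log, list(sprintf(
    "correct_bond_order_after_addition: demoted %d double bond(s)", changed)))
  state
}

#' Assign formal charges from valence bookkeeping
#'
#' Sets `formal_charge = round(bond-order sum + implicit H) - closest allowed
#' valence`: a nitrogen with four single bonds gets +1, a carboxylate oxygen
#' with one single bond and no hydrogen gets -1, atoms matching an allowed
#' valence get 0. Implicit hydrogens are counted via the component
#' definition.
#'
#' @param state a `PipelineState` with bond orders present.
#' @param dict component dictionary.
#' @param valences valence table.
#' @return the updated state.
#' @export
assign_formal_charges <- function(state, dict = list(),
                                  valences = default_valence_table()) {
  a <- state$table$atoms
  osum <- order_sums(state$table)
  ih <- if (length(dict)) implicit_h_counts(state$table, dict) else
    stats::setNames(integer(nrow(a)), a$atom_uid)
  for (i in seq_len(nrow(a))) {
    el <- a$element[i]
    v <- valences[[el]]
    if (is.null(v)) {
      if (el %in% c(names(covalent_radii())))
        next  # metals etc.: leave deposited charge untouched
      stop("element ", el, " missing from valence table (atom_uid ",
           a$atom_uid[i], ")")
    }
    total <- round(osum[as.character(a$atom_uid[i])] +
                     ih[as.character(a$atom_uid[i])])
    if (total == 0) next  # isolated atom (e.g. placeholder): leave as-is
    vstar <- v[which.min(abs(total - v))]
    state$table$atoms$formal_charge[i] <- as.integer(total - vstar)
  }
  state
}

#' Deduplicate partial-occupancy ligand copies at symmetry centers
#'
#' A ligand sitting on a crystallographic symmetry axis is often deposited as
#' several overlapping partial-occupancy copies. Among non-polymer residues
#' sharing a comp_id with mean occupancy <= 0.5 whose centroids fall within
#' `centroid_tol` of each other, exactly one copy is kept (highest mean
#' occupancy, tie: lowest res_index). Everything else is untouched.
#'
#' @param state a `PipelineState` with coordinates present.
#' @param centroid_tol centroid distance tolerance in angstroms.
#' @return the updated state.
#' @export
deduplicate_symmetry_ligands <- function(state, centroid_tol = 1.0) {
  a <- state$table$atoms
  lig <- a[!is_polymer_comp(a$comp_id) & a$is_resolved, , drop = FALSE]
  if (!nrow(lig)) return(state)
  keys <- unique(residue_key(lig))
  info <- do.call(rbind, lapply(keys, function(k) {
    rows <- lig[residue_key(lig) == k, , drop = FALSE]
    data.frame(key = k, comp_id = rows$comp_id[1], res_index = rows$res_index[1],
               occ = mean(rows$occupancy),
               cx = mean(rows$x), cy = mean(rows$y), cz = mean(rows$z),
               stringsAsFactors = FALSE)
  }))
  doomed_keys <- character()
  for (cid in unique(info$comp_id)) {
    cand <- info[info$comp_id == cid & info$occ <= 0.5, , drop = FALSE]
    if (nrow(cand) < 2L) next
    # group candidates whose centroids overlap within tolerance
    used <- rep(FALSE, nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (used[i]) next
      d <- sqrt((cand$cx - cand$cx[i])^2 + (cand$cy - cand$cy[i])^2 +
                  (cand$cz - cand$cz[i])^2)
      grp <- which(d <= centroid_tol & !used)
      used[grp] <- TRUE
      if (length(grp) < 2L) next
      ord <- grp[order(-cand$occ[grp], cand$res_index[grp])]
      doomed_keys <- c(doomed_keys, cand$key[ord[-1]])
    }
  }
  if (length(doomed_keys)) {
    uids <- a$atom_uid[residue_key(a) %in% doomed_keys]
    state <- delete_atoms(state, uids)
    state$log <- c(state$log, list(sprintf(
      "deduplicate_symmetry_ligands: removed %d duplicate copy/copies",
      length(doomed_keys))))
  }
  state
}

#' Impute missing intra-residue heavy atoms from ideal coordinates
#'
#' Residues with at least three resolved heavy atoms shared with their
#' component's ideal coordinates get their missing heavy atoms placed by
#' least-squares rigid superposition of the ideal fragment onto the resolved
#' atoms (proper rotation only). Placed atoms are appended with
#' `is_resolved = FALSE` and recorded in `extras$imputed`. Residues with
#' fewer than three shared atoms are reported in the log and left alone.
#'
#' @param state a `PipelineState`.
#' @param dict component dictionary with ideal coordinates.
#' @return the updated state.
#' @export
impute_missing_intra_residue <- function(state, dict) {
  a <- state$table$atoms
  appended <- list()
  skipped <- character()
  for (key in unique(residue_key(a))) {
    rows <- a[residue_key(a) == key, , drop = FALSE]
    def <- dict[[rows$comp_id[1]]]
    if (is.null(def)) stop("no component definition for ", rows$comp_id[1])
    ideal <- def$atoms[is.finite(def$atoms$ix) &
                         !(toupper(def$atoms$element) %in% c("H", "D")) &
                         !def$atoms$is_leaving, , drop = FALSE]
    if (!nrow(ideal)) next
    have <- rows[rows$is_resolved & rows$atom_name %in% ideal$name, , drop = FALSE]
    missing_names <- setdiff(ideal$name, rows$atom_name[rows$is_resolved])
    # also fill unresolved placeholders already in the table
    ph <- rows[!rows$is_resolved & !is.finite(rows$x), , drop = FALSE]
    if (!length(missing_names) && !nrow(ph)) next
    if (nrow(have) < 3L) { skipped <- c(skipped, key); next }
    fit <- kabsch_transform(
      as.matrix(ideal[match(have$atom_name, ideal$name), c("ix", "iy", "iz")]),
      cbind(have$x, have$y, have$z))
    place <- function(nms) {
      src <- ideal[match(nms, ideal$name), , drop = FALSE]
      sweep(as.matrix(src[, c("ix", "iy", "iz")]) %*% fit$R, 2, fit$t, "+")
    }
    fill_ph <- intersect(ph$atom_name, ideal$name)
    if (length(fill_ph)) {
      xyz <- place(fill_ph)
      idx <- match(rows$atom_uid[match(fill_ph, rows$atom_name)],
                   state$table$atoms$atom_uid)
      state$table$atoms$x[idx] <- xyz[, 1]
      state$table$atoms$y[idx] <- xyz[, 2]
      state$table$atoms$z[idx] <- xyz[, 3]
      appended[[length(appended) + 1L]] <-
        state$table$atoms$atom_uid[idx]
    }
    new_names <- setdiff(missing_names, rows$atom_name)
    if (length(new_names)) {
      xyz <- place(new_names)
      uids <- next_uids(state$table, length(new_names))
      src <- ideal[match(new_names, ideal$name), , drop = FALSE]
      state$table$atoms <- rbind(state$table$atoms, data.frame(
        atom_uid = uids, chain_id = rows$chain_id[1],
        entity_id = rows$entity_id[1], res_index = rows$res_index[1],
        comp_id = rows$comp_id[1], atom_name = new_names,
        element = toupper(src$element), altloc = "", occupancy = 0,
        formal_charge = 0L, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
        is_resolved = FALSE, stringsAsFactors = FALSE))
      appended[[length(appended) + 1L]] <- uids
    }
  }
  if (length(appended)) {
    uids <- unlist(appended)
    state$extras$imputed <- union(as.integer(state$extras$imputed),
                                  as.integer(uids))
    state$log <- c(state$log, list(sprintf(
      "impute_missing_intra_residue: placed %d atom(s)", length(uids))))
  }
  if (length(skipped)) state$log <- c(state$log, list(paste0(
    "impute_missing_intra_residue: <3 shared resolved atoms, skipped: ",
    paste(gsub("\r", ":", skipped), collapse = ", "))))
  validate_atom_table(state$table)
  state
}

#' Least-squares rigid superposition (proper rotation)
#'
#' Returns the rotation `R` (det +1) and translation `t` minimizing
#' `|P R + t - Q|^2` over corresponding rows of `P` and `Q`.
#'
#' @param P,Q n x 3 matrices of corresponding points.
#' @return list with `R` (3x3) and `t` (length 3).
#' @keywords internal
kabsch_transform <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  list(R = R, t = as.numeric(cq - cp %*% R))
}
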