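# shared test utilities: tiny states built in code, random isometries, and
# independent brute-force oracles kept deliberately naive

# a state of CA-only pseudo-residues at given coordinates
point_state <- function(xyz, chain = "A", comp = "GLY", res = NULL) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (is.null(res)) res <- seq_len(n)
  pipeline_state(atom_table(data.frame(
    atom_uid = seq_len(n), chain_id = chain, entity_id = 1L,
    res_index = res, comp_id = comp, atom_name = "CA", element = "C",
    altloc = "", occupancy = 1, formal_charge = 0L,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], is_resolved = TRUE,
    stringsAsFactors = FALSE)))
}

# random proper rotation matrix (QR with det correction)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid <- function(state, R = random_rotation(),
                        t = stats::rnorm(3, sd = 5)) {
  xyz <- as.matrix(state$table$atoms[, c("x", "y", "z")]) %*% R
  state$table$atoms$x <- xyz[, 1] + t[1]
  state$table$atoms$y <- xyz[, 2] + t[2]
  state$table$atoms$z <- xyz[, 3] + t[3]
  state
}

# ideal tetrahedral neighbor directions around the origin
tetrahedral_points <- function() {
  rbind(c(0, 0, 0), c(1, 1, 1) / sqrt(3), c(1, -1, -1) / sqrt(3),
        c(-1, 1, -1) / sqrt(3))
}

# independent brute-force lDDT: explicit double loops straight from the
# definition, no shared code with the library implementation
lddt_bruteforce <- function(pred_state, ref_state, inclusion_radius = 15,
                            thresholds = c(0.5, 1, 2, 4)) {
  ra <- ref_state$table$atoms
  ra <- ra[ra$is_resolved & !(ra$element %in% c("H", "D")), , drop = FALSE]
  pa <- pred_state$table$atoms
  pa <- pa[!(pa$element %in% c("H", "D")), , drop = FALSE]
  key <- function(df) paste(df$chain_id, df$res_index, df$atom_name)
  idx <- match(key(ra), key(pa))
  keep <- !is.na(idx)
  ra <- ra[keep, , drop = FALSE]
  pa <- pa[idx[keep], , drop = FALSE]
  n <- nrow(ra)
  per_atom <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    scores <- c()
    for (j in seq_len(n)) {
      if (i == j) next
      if (ra$chain_id[i] == ra$chain_id[j] &&
          ra$res_index[i] == ra$res_index[j]) next
      dr <- sqrt((ra$x[i] - ra$x[j])^2 + (ra$y[i] - ra$y[j])^2 +
                   (ra$z[i] - ra$z[j])^2)
      if (dr >= inclusion_radius) next
      dp <- sqrt((pa$x[i] - pa$x[j])^2 + (pa$y[i] - pa$y[j])^2 +
                   (pa$z[i] - pa$z[j])^2)
      scores <- c(scores, sum(abs(dp - dr) < thresholds) / length(thresholds))
    }
    if (length(scores)) per_atom[i] <- mean(scores)
  }
  mean(per_atom, na.rm = TRUE)
}

# random two-chain structure with residue structure, for lDDT oracle checks
random_fixture_state <- function(n_atoms, seed) {
  set.seed(seed)
  n1 <- ceiling(n_atoms / 2)
  xyz <- rbind(matrix(stats::rnorm(3 * n1, sd = 4), ncol = 3),
               matrix(stats::rnorm(3 * (n_atoms - n1), sd = 4), ncol = 3) +
                 matrix(rep(c(6, 0, 0), each = n_atoms - n1), ncol = 3))
  pipeline_state(atom_table(data.frame(
    atom_uid = seq_len(n_atoms),
    chain_id = rep(c("A", "B"), c(n1, n_atoms - n1)),
    entity_id = rep(1:2, c(n1, n_atoms - n1)),
    res_index = rep(seq_len(ceiling(n_atoms / 3)), each = 3)[seq_len(n_atoms)],
    comp_id = "GLY", atom_name = paste0("X", seq_len(n_atoms)),
    element = "C", altloc = "", occupancy = 1, formal_charge = 0L,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], is_resolved = TRUE,
    stringsAsFactors = FALSE)))
}

# a ligand-only state built from a component's ideal coordinates
component_state <- function(comp_id, dict = builtin_components(),
                            chain = "L", heavy_only = TRUE) {
  def <- dict[[comp_id]]
  at <- def$atoms
  if (heavy_only) at <- at[!(at$element %in% c("H", "D")), , drop = FALSE]
  st <- pipeline_state(atom_table(data.frame(
    atom_uid = seq_len(nrow(at)), chain_id = chain, entity_id = 1L,
    res_index = 1L, comp_id = comp_id, atom_name = at$name,
    element = at$element, altloc = "", occupancy = 1,
    formal_charge = at$charge, x = at$ix, y = at$iy, z = at$iz,
    is_resolved = TRUE, stringsAsFactors = FALSE)))
  attach_intra_component_bonds(st, dict)
}

mark_unresolved <- function(state, res_indices, chain = NULL) {
  a <- state$table$atoms
  sel <- a$res_index %in% res_indices
  if (!is.null(chain)) sel <- sel & a$chain_id %in% chain
  state$table$atoms$is_resolved[sel] <- FALSE
  state$table$atoms$x[sel] <- NA_real_
  state$table$atoms$y[sel] <- NA_real_
  state$table$atoms$z[sel] <- NA_real_
  state$table$atoms$occupancy[sel] <- 0
  state
}
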