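# Chirality representation: stereocenters are encoded by the signed angle
# between one substituent direction and the plane of the other two. The sign
# flips under mirror reflection and is invariant under proper isometries, so
# it cleanly separates enantiomers; the squared error against the ideal
# tetrahedral angle yields a per-atom gradient vector feature.

#' Ideal pyramidalization angle
#'
#' Magnitude of the signed chiral angle for perfect tetrahedral geometry:
#' `arcsin(sqrt(2/3))`, about 0.95532 rad (54.7356 degrees).
#'
#' @return numeric scalar, radians.
#' @export
ideal_chiral_angle <- function() asin(sqrt(2 / 3))

#' Signed chiral (pyramidal) angle
#'
#' With unit vectors u1, u2, u3 from the center to its three ranked
#' neighbors, returns `asin( u1 . (u2 x u3) / |u2 x u3| )`: the signed angle
#' between u1 and the plane of u2 and u3. Invariant under rotation and
#' translation; antisymmetric under reflection.
#'
#' @param center_xyz,n1_xyz,n2_xyz,n3_xyz numeric length-3 coordinates.
#' @return signed angle in radians.
#' @export
chiral_angle <- function(center_xyz, n1_xyz, n2_xyz, n3_xyz) {
  u1 <- n1_xyz - center_xyz; u1 <- u1 / sqrt(sum(u1^2))
  u2 <- n2_xyz - center_xyz; u2 <- u2 / sqrt(sum(u2^2))
  u3 <- n3_xyz - center_xyz; u3 <- u3 / sqrt(sum(u3^2))
  w <- c(u2[2] * u3[3] - u2[3] * u3[2],
         u2[3] * u3[1] - u2[1] * u3[3],
         u2[1] * u3[2] - u2[2] * u3[1])
  nw <- sqrt(sum(w^2))
  if (nw < 1e-8) stop("degenerate geometry: neighbors 2 and 3 colinear with center")
  s <- sum(u1 * w) / nw
  asin(max(-1, min(1, s)))
}

ATOMIC_NUMBER <- c(H = 1, D = 1, B = 5, C = 6, N = 7, O = 8, F = 9, NA_ = 11,
                   MG = 12, SI = 14, P = 15, S = 16, CL = 17, K = 19, CA = 20,
                   MN = 25, FE = 26, CO = 27, NI = 28, CU = 29, ZN = 30,
                   SE = 34, BR = 35, I = 53)

atomic_number <- function(el) {
  z <- ATOMIC_NUMBER[toupper(el)]
  ifelse(is.na(z), 0, z)
}

# deterministic neighbor-ranking key: higher atomic number first, then higher
# sum of the neighbor's own neighbors' atomic numbers, then atom_name
neighbor_rank_keys <- function(table, center_uid, neighbor_uids) {
  a <- table$atoms; b <- table$bonds
  z <- atomic_number(a$element[match(neighbor_uids, a$atom_uid)])
  zsum <- vapply(neighbor_uids, function(u) {
    nb <- c(b$atom_b[b$atom_a == u], b$atom_a[b$atom_b == u])
    nb <- setdiff(nb, center_uid)
    sum(atomic_number(a$element[match(nb, a$atom_uid)]))
  }, 1)
  nm <- a$atom_name[match(neighbor_uids, a$atom_uid)]
  list(z = z, zsum = zsum, name = nm,
       order = order(-z, -zsum, nm),
       key = paste(z, zsum, sep = "|"))
}

#' Find chiral centers in a structure
#'
#' Returns atoms carrying four distinct substituent branches (an implicit
#' hydrogen counts as one branch but never appears among the ranked
#' neighbors). Branches are ranked by a deterministic rule (atomic number,
#' then sum of the neighbors'-neighbors atomic numbers, then atom name);
#' heavy branches whose rank keys tie are ambiguous — such centers are
#' excluded and counted. The reference sign is computed from the component's
#' ideal coordinates when available, otherwise from the deposited
#' coordinates.
#'
#' @param state a `PipelineState` with bonds attached.
#' @param dict component dictionary (implicit hydrogens, ideal-coordinate
#'   reference signs); may be empty.
#' @return list with `centers` (list of `ChiralCenter`: center,
#'   ordered_neighbors, reference_sign, ideal_angle) and `n_ambiguous`.
#' @export
find_chiral_centers <- function(state, dict = list()) {
  tb <- state$table
  a <- tb$atoms; b <- tb$bonds
  ih <- if (length(dict)) implicit_h_counts(tb, dict) else
    stats::setNames(integer(nrow(a)), a$atom_uid)
  centers <- list()
  n_ambiguous <- 0L
  for (i in seq_len(nrow(a))) {
    uid <- a$atom_uid[i]
    nb <- c(b$atom_b[b$atom_a == uid], b$atom_a[b$atom_b == uid])
    el <- a$element[match(nb, a$atom_uid)]
    heavy <- nb[!(el %in% c("H", "D"))]
    n_h <- sum(el %in% c("H", "D")) + ih[as.character(uid)]
    if (length(heavy) + n_h != 4L || n_h > 1L) next
    if (length(heavy) < 3L) next
    rk <- neighbor_rank_keys(tb, uid, heavy)
    if (anyDuplicated(rk$key)) { n_ambiguous <- n_ambiguous + 1L; next }
    ordered <- heavy[rk$order][1:3]
    ref_sign <- chiral_reference_sign(a[i, ], ordered, tb, dict)
    if (is.na(ref_sign)) { n_ambiguous <- n_ambiguous + 1L; next }
    centers[[length(centers) + 1L]] <- structure(
      list(center = uid, ordered_neighbors = ordered,
           reference_sign = ref_sign, ideal_angle = ref_sign * ideal_chiral_angle()),
      class = "ChiralCenter")
  }
  list(centers = centers, n_ambiguous = n_ambiguous)
}

chiral_reference_sign <- function(center_row, ordered_uids, table, dict) {
  a <- table$atoms
  def <- dict[[center_row$comp_id]]
  nb_rows <- a[match(ordered_uids, a$atom_uid), , drop = FALSE]
  same_res <- all(residue_key(nb_rows) == residue_key(center_row))
  if (!is.null(def) && same_res) {
    nm <- c(center_row$atom_name, nb_rows$atom_name)
    idx <- match(nm, def$atoms$name)
    if (!anyNA(idx)) {
      xyz <- as.matrix(def$atoms[idx, c("ix", "iy", "iz")])
      if (all(is.finite(xyz)))
        return(sign(chiral_angle(xyz[1, ], xyz[2, ], xyz[3, ], xyz[4, ])))
    }
  }
  pts <- rbind(c(center_row$x, center_row$y, center_row$z),
               cbind(nb_rows$x, nb_rows$y, nb_rows$z))
  if (!all(is.finite(pts))) return(NA_real_)
  sign(chiral_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ]))
}

#' Gradient feature of the chiral-angle error
#'
#' For `E = (theta(x) - ideal_angle)^2` with `theta` the signed chiral angle,
#' returns the analytic gradient of E with respect to each of the four atom
#' positions (center and ranked neighbors). The four vectors sum to zero
#' (translation invariance) and vanish exactly at the ideal angle.
#'
#' @param center a `ChiralCenter` (carries the signed ideal angle).
#' @param xyz 4 x 3 matrix: rows center, n1, n2, n3.
#' @return `ChiralFeature`: list with `grad` (4 x 3 matrix, rows named
#'   center/n1/n2/n3), `theta` and `error`.
#' @export
chiral_error_gradient <- function(center, xyz) {
  stopifnot(nrow(xyz) == 4L, ncol(xyz) == 3L)
  c0 <- xyz[1, ]
  d1 <- xyz[2, ] - c0; r1 <- sqrt(sum(d1^2)); u1 <- d1 / r1
  d2 <- xyz[3, ] - c0; r2 <- sqrt(sum(d2^2)); u2 <- d2 / r2
  d3 <- xyz[4, ] - c0; r3 <- sqrt(sum(d3^2)); u3 <- d3 / r3
  cross <- function(p, q) c(p[2] * q[3] - p[3] * q[2],
                            p[3] * q[1] - p[1] * q[3],
                            p[1] * q[2] - p[2] * q[1])
  v <- cross(u2, u3)
  s <- sqrt(sum(v^2))
  if (s < 1e-8) stop("degenerate geometry: neighbors 2 and 3 colinear with center")
  n <- v / s
  g <- sum(u1 * n)
  theta <- asin(max(-1, min(1, g)))
  # dg/du_i, then project through the unit-vector Jacobian (I - u u^T)/r
  p <- (u1 - g * n) / s
  g_u1 <- n
  g_u2 <- cross(u3, p)   # since dv = -[u3]x du2 and grad = [u3]x p
  g_u3 <- cross(p, u2)   # since dv =  [u2]x du3 and grad = -[u2]x p
  proj <- function(gu, u, r) (gu - sum(gu * u) * u) / r
  g_x1 <- proj(g_u1, u1, r1)
  g_x2 <- proj(g_u2, u2, r2)
  g_x3 <- proj(g_u3, u3, r3)
  dE_dtheta <- 2 * (theta - center$ideal_angle)
  denom <- sqrt(max(1 - g^2, 1e-12))
  scale <- dE_dtheta / denom
  grad <- rbind(center = -(g_x1 + g_x2 + g_x3) * scale,
                n1 = g_x1 * scale, n2 = g_x2 * scale, n3 = g_x3 * scale)
  structure(list(grad = grad, theta = theta,
                 error = (theta - center$ideal_angle)^2),
            class = "ChiralFeature")
}

#' Mirror a structure
#'
#' Negates every x coordinate. Pairwise distances are preserved, every
#' chiral-angle sign flips, and a second application restores the original
#' coordinates exactly.
#'
#' @param state a `PipelineState`.
#' @return the mirrored state.
#' @export
invert_structure <- function(state) {
  state$table$atoms$x <- -state$table$atoms$x
  state$extras$inverted <- !isTRUE(state$extras$inverted)
  state
}

#' Stochastic mirror-inversion augmentation
#'
#' With probability `p` (seeded Bernoulli per example) returns the mirrored
#' structure, otherwise the input unchanged; the decision is logged. Used at
#' train time to teach a model to read chiral features rather than memorize
#' one handedness; the reference rate is 2% of examples.
#'
#' @param state a `PipelineState`.
#' @param p inversion probability in \[0,1\].
#' @param seed integer seed; defaults to the state's `rng_seed` combined with
#'   the transform name via [derive_seed()].
#' @return the (possibly mirrored) state.
#' @export
sample_inversion_augmentation <- function(state, p = 0.02, seed = NULL) {
  stopifnot(p >= 0, p <= 1)
  if (is.null(seed)) seed <- derive_seed(state$rng_seed, "sample_inversion_augmentation")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  flip <- stats::runif(1) < p
  state$log <- c(state$log, list(sprintf(
    "sample_inversion_augmentation: p=%.4f seed=%d -> %s", p, seed,
    if (flip) "inverted" else "kept")))
  if (flip) invert_structure(state) else state
}

#' Chiral-center accuracy with cluster-mean reporting
#'
#' A center is predicted correctly iff the sign of its chiral angle in the
#' prediction equals the reference sign derived from the reference structure.
#' Per-molecule percentages (a molecule is one residue bearing centers) are
#' averaged within each cluster, and the overall value is the unweighted mean
#' across clusters.
#'
#' @param pred_state,ref_state states sharing atom correspondence by
#'   (chain, res_index, atom_name).
#' @param clusters `ClusterAssignment` over molecule comp_ids (see
#'   [cluster_members()]); `NULL` clusters molecules by comp_id.
#' @param dict component dictionary passed to [find_chiral_centers()].
#' @return list with `overall`, `per_cluster`, `per_molecule`, `n_centers`,
#'   `n_ambiguous`.
#' @export
chiral_center_accuracy <- function(pred_state, ref_state, clusters = NULL,
                                   dict = list()) {
  found <- find_chiral_centers(ref_state, dict)
  if (!length(found$centers))
    stop("reference structure has no chiral centers (n_ambiguous = ",
         found$n_ambiguous, ")")
  ra <- ref_state$table$atoms
  pa <- pred_state$table$atoms
  pred_uid <- function(ref_uid) {
    r <- ra[match(ref_uid, ra$atom_uid), ]
    hit <- pa$atom_uid[pa$chain_id == r$chain_id & pa$res_index == r$res_index &
                         pa$atom_name == r$atom_name]
    if (length(hit)) hit[1] else NA_integer_
  }
  mol_of <- character(); comp_of <- character(); correct <- logical()
  for (cc in found$centers) {
    r <- ra[match(cc$center, ra$atom_uid), ]
    uids_p <- vapply(c(cc$center, cc$ordered_neighbors), pred_uid, 1L)
    if (anyNA(uids_p)) next
    # the ground truth is the deposited reference geometry (a D-residue must
    # be scored as D); the ideal-coordinate sign is only a fallback
    ref_xyz <- coords_matrix(ref_state$table, c(cc$center, cc$ordered_neighbors))
    ref_sign <- if (all(is.finite(ref_xyz)))
      sign(chiral_angle(ref_xyz[1, ], ref_xyz[2, ], ref_xyz[3, ], ref_xyz[4, ]))
    else cc$reference_sign
    xyz <- coords_matrix(pred_state$table, uids_p)
    th <- chiral_angle(xyz[1, ], xyz[2, ], xyz[3, ], xyz[4, ])
    mol_of <- c(mol_of, residue_key(r))
    comp_of <- c(comp_of, r$comp_id)
    correct <- c(correct, sign(th) == ref_sign)
  }
  per_molecule <- tapply(correct, mol_of, mean)
  mol_comp <- tapply(comp_of, mol_of, `[`, 1)
  if (is.null(clusters))
    clusters <- cluster_members(unname(mol_comp), mode = "ccd_identity",
                                ids = names(per_molecule))
  cl_of <- clusters$membership[names(per_molecule)]
  if (anyNA(cl_of))
    stop("scored molecule(s) missing from cluster assignment: ",
         paste(names(per_molecule)[is.na(cl_of)], collapse = ", "))
  per_cluster <- tapply(as.numeric(per_molecule), cl_of, mean)
  list(overall = mean(per_cluster), per_cluster = per_cluster,
       per_molecule = per_molecule, n_centers = length(correct),
       n_ambiguous = found$n_ambiguous)
}
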