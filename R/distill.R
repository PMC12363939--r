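# Disorder distillation: unresolved regions are filled with ideal-geometry
# extended backbones built in internal coordinates (NeRF placement), so that
# exposure statistics over formerly unresolved residues become computable.

#' Ideal backbone geometry
#'
#' Bond lengths (angstroms), bond angles and torsions (degrees) for the
#' peptide backbone. The default torsions phi = psi = omega = 180 give the
#' maximally extended chain; beta-strand values are a reasonable alternative
#' via the arguments.
#'
#' @param phi,psi,omega backbone torsions in degrees.
#' @return list of class `IdealGeometry`.
#' @export
ideal_geometry <- function(phi = 180, psi = 180, omega = 180) {
  g <- list(
    len_n_ca = 1.458, len_ca_c = 1.525, len_c_n = 1.329, len_c_o = 1.231,
    ang_n_ca_c = 111.0, ang_ca_c_n = 117.2, ang_c_n_ca = 121.7,
    ang_ca_c_o = 120.5,
    phi = phi, psi = psi, omega = omega)
  stopifnot(all(unlist(g[1:4]) > 0),
            all(unlist(g[5:8]) > 0 & unlist(g[5:8]) < 180))
  structure(g, class = "IdealGeometry")
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Places atom D given reference atoms A, B, C, the bond length |C-D|, the
#' bond angle B-C-D and the torsion A-B-C-D.
#'
#' @param a,b,c length-3 coordinates of the three reference atoms.
#' @param length bond length in angstroms.
#' @param angle bond angle in degrees.
#' @param torsion dihedral in degrees.
#' @return length-3 coordinates of D.
#' @export
place_atom <- function(a, b, c, length, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-8) stop("colinear reference atoms for internal-coordinate placement")
  n <- n / nn
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-length * cos(ang), length * sin(ang) * cos(tor),
          length * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Measure a dihedral angle
#'
#' @param p1,p2,p3,p4 length-3 coordinates.
#' @return torsion in degrees in (-180, 180].
#' @export
measure_torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  m1 <- cr(n1, b2 / sqrt(sum(b2^2)))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

#' Build a backbone chain in internal coordinates
#'
#' Sequentially places N, CA, C (and O) for `n_residues` from
#' (distance, angle, torsion) triples: N(i) uses psi(i-1), CA(i) uses
#' omega(i), C(i) uses phi(i); O(i) sits in the i-th residue frame at
#' psi(i) + 180. Realized internal coordinates match the requested geometry
#' to numerical precision. With an `anchor` (the N, CA, C of the residue
#' preceding the chain, non-colinear) the chain continues from it; without,
#' residue 1 is laid down in a canonical frame at the origin.
#'
#' @param geometry an [ideal_geometry()].
#' @param n_residues number of residues to place (>= 1).
#' @param anchor optional 3 x 3 matrix, rows = N, CA, C of the preceding
#'   residue.
#' @param place_o also place carbonyl O atoms (default TRUE).
#' @param torsions optional data.frame with per-residue `phi`, `psi`,
#'   `omega` columns overriding the geometry constants.
#' @return data.frame with columns `res` (1-based), `atom_name`, `x`, `y`,
#'   `z`.
#' @export
place_chain_internal <- function(geometry, n_residues, anchor = NULL,
                                 place_o = TRUE, torsions = NULL) {
  stopifnot(inherits(geometry, "IdealGeometry"), n_residues >= 1)
  tor <- function(i, what) {
    i <- max(1L, min(i, n_residues))
    if (!is.null(torsions) && what %in% names(torsions)) torsions[[what]][i]
    else geometry[[what]]
  }
  frames <- vector("list", n_residues)  # each: list(N=, CA=, C=)
  if (is.null(anchor)) {
    N <- c(0, 0, 0)
    CA <- c(geometry$len_n_ca, 0, 0)
    ang <- geometry$ang_n_ca_c * pi / 180
    C <- CA + geometry$len_ca_c * c(-cos(ang), sin(ang), 0)
    frames[[1]] <- list(N = N, CA = CA, C = C)
    prev <- frames[[1]]
    start <- 2L
    prev_psi_idx <- 1L
  } else {
    anchor <- as.matrix(anchor)
    stopifnot(nrow(anchor) == 3L, ncol(anchor) == 3L)
    v1 <- anchor[2, ] - anchor[1, ]; v2 <- anchor[3, ] - anchor[2, ]
    cr <- c(v1[2] * v2[3] - v1[3] * v2[2], v1[3] * v2[1] - v1[1] * v2[3],
            v1[1] * v2[2] - v1[2] * v2[1])
    if (sqrt(sum(cr^2)) < 1e-8) stop("colinear anchor atoms")
    prev <- list(N = anchor[1, ], CA = anchor[2, ], C = anchor[3, ])
    start <- 1L
    prev_psi_idx <- 1L  # psi for the anchor->first link: use residue 1's value
  }
  for (i in start:n_residues) {
    N <- place_atom(prev$N, prev$CA, prev$C, geometry$len_c_n,
                    geometry$ang_ca_c_n,
                    tor(if (i == start && !is.null(anchor)) 1L else i - 1L, "psi"))
    CA <- place_atom(prev$CA, prev$C, N, geometry$len_n_ca,
                     geometry$ang_c_n_ca, tor(i, "omega"))
    C <- place_atom(prev$C, N, CA, geometry$len_ca_c,
                    geometry$ang_n_ca_c, tor(i, "phi"))
    frames[[i]] <- list(N = N, CA = CA, C = C)
    prev <- frames[[i]]
  }
  rows <- list()
  for (i in seq_len(n_residues)) {
    f <- frames[[i]]
    for (nm in c("N", "CA", "C")) rows[[length(rows) + 1L]] <- data.frame(
      res = i, atom_name = nm, x = f[[nm]][1], y = f[[nm]][2], z = f[[nm]][3],
      stringsAsFactors = FALSE)
    if (place_o) {
      O <- place_atom(f$N, f$CA, f$C, geometry$len_c_o, geometry$ang_ca_c_o,
                      tor(i, "psi") + 180)
      rows[[length(rows) + 1L]] <- data.frame(
        res = i, atom_name = "O", x = O[1], y = O[2], z = O[3],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# geometry of the chain walked C-terminus -> N-terminus: the two backbone
# bond lengths and the two peptide-unit angles swap roles
reverse_geometry <- function(g) {
  r <- g
  r$len_n_ca <- g$len_ca_c
  r$len_ca_c <- g$len_n_ca
  r$ang_ca_c_n <- g$ang_c_n_ca
  r$ang_c_n_ca <- g$ang_ca_c_n
  r
}

#' Extend unresolved regions with ideal extended backbones
#'
#' Every unresolved residue run gains backbone coordinates from the
#' internal-coordinate builder, grown from the nearest resolved anchor
#' residue in its chain: internal gaps and C-terminal tails grow forward
#' from the N-side anchor; N-terminal tails grow backward from the first
#' resolved residue (built along the reversed chain with the
#' correspondingly swapped geometry). If a placed backbone atom falls within
#' `clash_tol` of a resolved heavy atom, phi/psi are perturbed by a seeded
#' +/-20 degrees and the region is rebuilt, up to `max_retries` times; the
#' least-clashing attempt wins if none is clash-free. Placed atoms keep
#' `is_resolved = FALSE`, are recorded in `extras$imputed_extended`, and
#' resolved atoms are never moved. Re-running on an already-extended
#' structure changes nothing. Side chains of placed residues can afterwards
#' be imputed from component ideal coordinates via
#' [impute_missing_intra_residue()].
#'
#' @param state a `PipelineState` with unresolved placeholder residues.
#' @param geometry an [ideal_geometry()].
#' @param clash_tol clash distance in angstroms.
#' @param max_retries torsion-perturbation retries per region.
#' @param seed integer seed for the perturbations; defaults to a stream
#'   derived from the state's `rng_seed`.
#' @return the updated state.
#' @export
extend_disordered_regions <- function(state, geometry = ideal_geometry(),
                                      clash_tol = 2.0, max_retries = 10,
                                      seed = NULL) {
  if (is.null(seed)) seed <- derive_seed(state$rng_seed, "extend_disordered_regions")
  a <- state$table$atoms
  old_rng <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_rng)) assign(".Random.seed", old_rng, globalenv()))
  set.seed(seed)
  placed_any <- integer()
  for (ch in unique(a$chain_id)) {
    ca <- a[a$chain_id == ch, , drop = FALSE]
    has_coords <- tapply(is.finite(ca$x) &
                           ca$atom_name %in% c("N", "CA", "C"),
                         ca$res_index, any)
    idx <- as.integer(names(has_coords))
    todo <- sort(idx[!has_coords])
    if (!length(todo)) next
    anchored <- idx[has_coords]
    if (!length(anchored)) {
      state$log <- c(state$log, list(paste0(
        "extend_disordered_regions: chain ", ch,
        " has no resolved anchor; skipped")))
      next
    }
    runs <- split(todo, cumsum(c(1, diff(todo) != 1)))
    for (run in runs) {
      n_side <- suppressWarnings(max(anchored[anchored < min(run)]))
      backward <- !is.finite(n_side)
      anchor_res <- if (backward) min(anchored[anchored > max(run)]) else n_side
      anc_rows <- ca[ca$res_index == anchor_res, , drop = FALSE]
      get_xyz <- function(nm) {
        r <- anc_rows[anc_rows$atom_name == nm & is.finite(anc_rows$x), ,
                      drop = FALSE]
        if (!nrow(r)) return(NULL)
        c(r$x[1], r$y[1], r$z[1])
      }
      Nx <- get_xyz("N"); CAx <- get_xyz("CA"); Cx <- get_xyz("C")
      if (is.null(Nx) || is.null(CAx) || is.null(Cx)) {
        state$log <- c(state$log, list(paste0(
          "extend_disordered_regions: anchor residue ", ch, ":", anchor_res,
          " lacks a full backbone frame; run skipped")))
        next
      }
      nres <- length(run)
      base_geom <- if (backward) reverse_geometry(geometry) else geometry
      anchor <- if (backward) rbind(Cx, CAx, Nx) else rbind(Nx, CAx, Cx)
      # the junction peptide bond to the anchor residue is covalent, not a
      # clash: exclude the anchor residue from the clash set
      anc_uid <- ca$atom_uid[ca$res_index == anchor_res]
      clash_xyz <- as.matrix(a[a$is_resolved & !(a$element %in% c("H", "D")) &
                                 is.finite(a$x) &
                                 !(a$atom_uid %in% anc_uid),
                               c("x", "y", "z")])
      best <- NULL; best_clashes <- Inf
      for (try in 0:max_retries) {
        g <- base_geom
        if (try > 0) {
          g$phi <- base_geom$phi + stats::runif(1, -20, 20)
          g$psi <- base_geom$psi + stats::runif(1, -20, 20)
        }
        bb <- place_chain_internal(g, nres, anchor = anchor, place_o = FALSE)
        if (backward) {
          bb$atom_name <- c(N = "C", CA = "CA", C = "N")[bb$atom_name]
          bb$res <- max(run) + 1L - bb$res
        } else {
          bb$res <- min(run) - 1L + bb$res
        }
        # carbonyl O from each residue's own frame, trans to psi
        for (rr in unique(bb$res)) {
          f <- lapply(c("N", "CA", "C"), function(nm)
            as.numeric(bb[bb$res == rr & bb$atom_name == nm, c("x", "y", "z")]))
          O <- place_atom(f[[1]], f[[2]], f[[3]], geometry$len_c_o,
                          geometry$ang_ca_c_o, geometry$psi + 180)
          bb <- rbind(bb, data.frame(res = rr, atom_name = "O", x = O[1],
                                     y = O[2], z = O[3],
                                     stringsAsFactors = FALSE))
        }
        n_clash <- if (nrow(clash_xyz)) {
          sum(apply(as.matrix(bb[, c("x", "y", "z")]), 1, function(p)
            any(rowSums(sweep(clash_xyz, 2, p)^2) < clash_tol^2)))
        } else 0L
        if (n_clash < best_clashes) { best <- bb; best_clashes <- n_clash }
        if (n_clash == 0L) break
      }
      bb <- best
      for (r in seq_len(nrow(bb))) {
        sel <- which(state$table$atoms$chain_id == ch &
                       state$table$atoms$res_index == bb$res[r] &
                       state$table$atoms$atom_name == bb$atom_name[r])
        if (!length(sel)) next
        if (is.finite(state$table$atoms$x[sel[1]])) next
        state$table$atoms$x[sel[1]] <- bb$x[r]
        state$table$atoms$y[sel[1]] <- bb$y[r]
        state$table$atoms$z[sel[1]] <- bb$z[r]
        placed_any <- c(placed_any, state$table$atoms$atom_uid[sel[1]])
      }
    }
  }
  if (length(placed_any)) {
    state$extras$imputed_extended <- union(
      as.integer(state$extras$imputed_extended), placed_any)
    state$log <- c(state$log, list(sprintf(
      "extend_disordered_regions: placed %d backbone atom(s)",
      length(placed_any))))
  }
  validate_atom_table(state$table)
  state
}
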