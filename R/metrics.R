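# Evaluation stack: all-atom lDDT, interface lDDT, backbone RMSD,
# Shrake-Rupley solvent accessibility, relative accessibility over residue
# regions, and the clustering / cluster-mean reporting protocol.

#' Atom correspondence between two states
#'
#' Matches atoms by (chain_id, res_index, atom_name); only atoms resolved in
#' the reference are considered.
#'
#' @param pred_state,ref_state `PipelineState`s.
#' @param heavy_only drop hydrogens (default TRUE).
#' @return data.frame with columns `ref_uid`, `pred_uid`, `chain_id`,
#'   `res_index`, `atom_name`, `entity_id`.
#' @keywords internal
atom_correspondence <- function(pred_state, ref_state, heavy_only = TRUE) {
  ra <- ref_state$table$atoms
  pa <- pred_state$table$atoms
  ra <- ra[ra$is_resolved, , drop = FALSE]
  if (heavy_only) {
    ra <- ra[!(ra$element %in% c("H", "D")), , drop = FALSE]
    pa <- pa[!(pa$element %in% c("H", "D")), , drop = FALSE]
  }
  key <- function(df) paste(df$chain_id, df$res_index, df$atom_name, sep = "\r")
  idx <- match(key(ra), key(pa))
  ok <- !is.na(idx) & is.finite(pa$x[idx])
  data.frame(ref_uid = ra$atom_uid[ok], pred_uid = pa$atom_uid[idx[ok]],
             chain_id = ra$chain_id[ok], res_index = ra$res_index[ok],
             atom_name = ra$atom_name[ok], entity_id = ra$entity_id[ok],
             stringsAsFactors = FALSE)
}

#' Local distance difference test (lDDT)
#'
#' Superposition-free accuracy score. Reference pairs are heavy-atom pairs in
#' different residues whose reference distance is below `inclusion_radius`
#' (and which pass `pair_filter`, when given). Each pair scores the fraction
#' of `thresholds` within which the predicted distance deviation falls; each
#' atom scores the mean over its pairs; the global score is the mean over
#' atoms with at least one pair.
#'
#' @param pred_state,ref_state `PipelineState`s; correspondence by
#'   (chain, res_index, atom_name), reference-resolved atoms only.
#' @param inclusion_radius reference-distance cutoff in angstroms.
#' @param thresholds deviation thresholds in angstroms.
#' @param pair_filter optional `function(corr_i, corr_j)` over rows of the
#'   correspondence table returning TRUE for pairs to score.
#' @return `LDDTResult`: list with `global_score`, `per_atom_scores` (named
#'   by ref atom_uid), `n_pairs`, `params`.
#' @export
lddt <- function(pred_state, ref_state, inclusion_radius = 15,
                 thresholds = c(0.5, 1, 2, 4), pair_filter = NULL) {
  corr <- atom_correspondence(pred_state, ref_state)
  if (!nrow(corr)) stop("no corresponding atoms between prediction and reference")
  xyz_r <- coords_matrix(ref_state$table, corr$ref_uid)
  xyz_p <- coords_matrix(pred_state$table, corr$pred_uid)
  Dr <- as.matrix(stats::dist(xyz_r))
  Dp <- as.matrix(stats::dist(xyz_p))
  n <- nrow(corr)
  res_key <- paste(corr$chain_id, corr$res_index, sep = "\r")
  same_res <- outer(res_key, res_key, "==")
  sel <- Dr < inclusion_radius & !same_res
  diag(sel) <- FALSE
  if (!is.null(pair_filter)) {
    pf <- matrix(FALSE, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      pf[i, j] <- pf[j, i] <- isTRUE(pair_filter(corr[i, ], corr[j, ]))
    }
    sel <- sel & pf
  }
  if (!any(sel)) stop("zero reference pairs under the given filter/radius")
  dev <- abs(Dp - Dr)
  frac <- matrix(0, n, n)
  for (t in thresholds) frac <- frac + (dev < t)
  frac <- frac / length(thresholds)
  per_atom <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ps <- frac[i, sel[i, ]]
    if (length(ps)) per_atom[i] <- mean(ps)
  }
  names(per_atom) <- corr$ref_uid
  scored <- !is.na(per_atom)
  structure(list(global_score = mean(per_atom[scored]),
                 per_atom_scores = per_atom,
                 n_pairs = sum(sel) / 2,
                 params = list(inclusion_radius = inclusion_radius,
                               thresholds = thresholds)),
            class = "LDDTResult")
}

#' @export
print.LDDTResult <- function(x, ...) {
  cat(sprintf("lDDT %.4f over %d pairs (radius %g A, thresholds %s)\n",
              x$global_score, x$n_pairs, x$params$inclusion_radius,
              paste(x$params$thresholds, collapse = "/")))
  invisible(x)
}

#' Interface lDDT between two groups
#'
#' [lddt()] restricted to pairs spanning the two groups; symmetric in
#' (group_a, group_b). Groups are chain_id vectors (or functions of a
#' correspondence row returning TRUE/FALSE) and must be disjoint.
#'
#' @param pred_state,ref_state `PipelineState`s.
#' @param group_a,group_b chain_id character vectors, or predicate functions
#'   over correspondence rows.
#' @param ... passed to [lddt()] (radius, thresholds).
#' @return `LDDTResult`. Raises a distinct "no interface" error when no
#'   cross-group pair lies within the inclusion radius.
#' @export
interface_lddt <- function(pred_state, ref_state, group_a, group_b, ...) {
  in_group <- function(g) {
    if (is.function(g)) g else function(row) row$chain_id %in% g
  }
  fa <- in_group(group_a); fb <- in_group(group_b)
  pf <- function(ri, rj) (fa(ri) && fb(rj)) || (fa(rj) && fb(ri))
  if (is.character(group_a) && is.character(group_b) &&
      length(intersect(group_a, group_b)))
    stop("groups must be disjoint")
  tryCatch(lddt(pred_state, ref_state, pair_filter = pf, ...),
           error = function(e) {
             if (grepl("zero reference pairs", conditionMessage(e)))
               stop("no interface: no cross-group pair within the inclusion radius",
                    call. = FALSE)
             stop(e)
           })
}

#' Backbone RMSD after optimal superposition
#'
#' Least-squares rigid superposition (rotation + translation, proper
#' rotation only — no reflection) of corresponding backbone atoms, then the
#' root-mean-square deviation, via `bio3d::rmsd(..., fit = TRUE)`. A
#' mirrored chiral structure therefore scores strictly positive.
#'
#' @param pred_state,ref_state `PipelineState`s.
#' @param atom_set backbone atom names to superpose (default CA only).
#' @return RMSD in angstroms.
#' @export
backbone_rmsd <- function(pred_state, ref_state, atom_set = "CA") {
  corr <- atom_correspondence(pred_state, ref_state)
  corr <- corr[corr$atom_name %in% atom_set, , drop = FALSE]
  if (nrow(corr) < 3L) stop("need at least 3 corresponding atoms, have ",
                            nrow(corr))
  xyz_r <- coords_matrix(ref_state$table, corr$ref_uid)
  xyz_p <- coords_matrix(pred_state$table, corr$pred_uid)
  bio3d::rmsd(as.vector(t(xyz_r)), as.vector(t(xyz_p)), fit = TRUE)
}

# Bondi van der Waals radii (angstroms); 1.7 fallback for unlisted elements
VDW_RADII <- c(H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
               P = 1.80, S = 1.80, CL = 1.75, SE = 1.90, BR = 1.85, I = 1.98,
               B = 1.92, SI = 2.10, NA_ = 2.27, MG = 1.73, K = 2.75,
               CA = 2.31, MN = 2.05, FE = 2.05, CO = 2.00, NI = 1.97,
               CU = 1.96, ZN = 2.01)

# deterministic unit sphere points (golden-spiral / Fibonacci lattice)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Sphere-sampling SASA per heavy atom: each atom's solvent sphere (van der
#' Waals radius + probe) is sampled at `n_sphere_points` deterministic
#' points; the accessible fraction is the share of points not buried inside
#' any neighbor's solvent sphere. Deterministic for a fixed point set.
#'
#' @param state a `PipelineState`.
#' @param probe_radius probe radius in angstroms (water: 1.4).
#' @param n_sphere_points points per atom.
#' @return named numeric vector of areas (A^2) per heavy-atom atom_uid.
#' @export
per_atom_sasa <- function(state, probe_radius = 1.4, n_sphere_points = 960) {
  a <- state$table$atoms
  a <- a[a$is_resolved & !(a$element %in% c("H", "D")) & is.finite(a$x), ,
         drop = FALSE]
  if (!nrow(a)) return(stats::setNames(numeric(), character()))
  xyz <- cbind(a$x, a$y, a$z)
  dup <- which(duplicated(round(xyz, 6)))
  if (length(dup)) {
    D <- as.matrix(stats::dist(xyz)); diag(D) <- Inf
    hit <- which(D < 1e-6, arr.ind = TRUE)
    if (nrow(hit)) stop("overlapping identical coordinates for atom_uid ",
                        paste(unique(a$atom_uid[hit[, 1]]), collapse = ", "))
  }
  r <- unname(VDW_RADII[a$element]); r[is.na(r)] <- 1.7
  R <- r + probe_radius
  pts <- sphere_points(n_sphere_points)
  n <- nrow(a)
  D2 <- as.matrix(stats::dist(xyz))^2
  out <- numeric(n)
  for (i in seq_len(n)) {
    nbr <- which(D2[i, ] < (R[i] + R)^2 & seq_len(n) != i)
    surf <- sweep(pts * R[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_sphere_points)
    for (j in nbr) {
      dj2 <- (surf[, 1] - xyz[j, 1])^2 + (surf[, 2] - xyz[j, 2])^2 +
        (surf[, 3] - xyz[j, 3])^2
      acc <- acc & dj2 > R[j]^2
      if (!any(acc)) break
    }
    out[i] <- 4 * pi * R[i]^2 * mean(acc)
  }
  stats::setNames(out, a$atom_uid)
}

#' Maximum accessible surface areas for residues
#'
#' Theoretical maximum ASA per residue type in an extended Gly-X-Gly
#' tripeptide (Tien et al. 2013 values), used to normalize residue SASA into
#' relative accessibility.
#'
#' @return named numeric vector (A^2).
#' @export
max_asa_table <- function() {
  c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167, GLN = 225,
    GLU = 223, GLY = 104, HIS = 224, ILE = 197, LEU = 201, LYS = 236,
    MET = 224, PHE = 240, PRO = 159, SER = 155, THR = 172, TRP = 285,
    TYR = 263, VAL = 174)
}

#' Mean relative accessible surface area over a residue region
#'
#' Per-residue RASA = (sum of the residue's heavy-atom SASA) / (maximum ASA
#' for that residue type), clipped to \[0,1\]; returns the mean over the
#' region. SASA is computed in the context of the whole structure, so a
#' buried region scores low and an extended, exposed region scores high.
#'
#' @param state a `PipelineState` whose region residues have coordinates.
#' @param region data.frame with columns `chain_id`, `res_index` selecting
#'   residues.
#' @param max_asa named vector of per-residue-type maxima.
#' @param sasa optional precomputed [per_atom_sasa()] result.
#' @return mean RASA in \[0,1\].
#' @export
mean_rasa <- function(state, region, max_asa = max_asa_table(), sasa = NULL) {
  if (!nrow(region)) stop("empty region")
  if (is.null(sasa)) sasa <- per_atom_sasa(state)
  a <- state$table$atoms
  vals <- numeric(nrow(region))
  for (i in seq_len(nrow(region))) {
    rows <- a[a$chain_id == region$chain_id[i] &
                a$res_index == region$res_index[i], , drop = FALSE]
    if (!nrow(rows)) stop("region residue ", region$chain_id[i], ":",
                          region$res_index[i], " not in structure")
    comp <- rows$comp_id[1]
    if (!comp %in% names(max_asa)) stop("residue type ", comp,
                                        " missing from max ASA table")
    s <- sasa[as.character(rows$atom_uid)]
    vals[i] <- min(1, max(0, sum(s, na.rm = TRUE) / max_asa[[comp]]))
  }
  mean(vals)
}

#' Cluster members for cluster-mean reporting
#'
#' `ccd_identity` partitions by exact comp_id — the protocol for non-polymer
#' members. `sequence_identity_40` greedily clusters polymer sequences:
#' members are processed by descending length (ties by id), each joining the
#' first existing cluster whose representative aligns with global-alignment
#' identity (matches / alignment length, gaps included) >= 0.40, else
#' founding a new cluster.
#'
#' @param items character vector: comp_ids or sequences.
#' @param mode `"ccd_identity"` or `"sequence_identity_40"`.
#' @param ids optional member ids (default: `items` themselves, made unique).
#' @param threshold identity threshold for sequence mode.
#' @return `ClusterAssignment`: list with `membership` (named id ->
#'   cluster id) and `representatives` (cluster id -> member id).
#' @export
cluster_members <- function(items, mode = c("ccd_identity", "sequence_identity_40"),
                            ids = NULL, threshold = 0.40) {
  mode <- match.arg(mode)
  if (!length(items)) stop("empty input")
  if (is.null(ids)) ids <- make.unique(items)
  stopifnot(length(ids) == length(items))
  if (mode == "ccd_identity") {
    membership <- stats::setNames(items, ids)
    reps <- stats::setNames(ids[!duplicated(items)], items[!duplicated(items)])
    return(structure(list(membership = membership, representatives = reps),
                     class = "ClusterAssignment"))
  }
  ord <- order(-nchar(items), ids)
  membership <- stats::setNames(rep(NA_character_, length(items)), ids)
  reps <- character()
  rep_seq <- character()
  for (k in ord) {
    placed <- FALSE
    for (cl in names(reps)) {
      if (seq_identity_global(items[k], rep_seq[[cl]]) >= threshold) {
        membership[ids[k]] <- cl
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      cl <- paste0("cluster", length(reps) + 1L)
      reps[cl] <- ids[k]
      rep_seq[cl] <- items[k]
      membership[ids[k]] <- cl
    }
  }
  structure(list(membership = membership, representatives = reps),
            class = "ClusterAssignment")
}

#' Global-alignment sequence identity
#'
#' Needleman-Wunsch global alignment (Biostrings); identity = matches
#' divided by full alignment length including gaps — the stricter,
#' deterministic denominator.
#'
#' @param s1,s2 sequences (character).
#' @return identity in \[0,1\].
#' @export
seq_identity_global <- function(s1, s2) {
  letters_all <- unique(strsplit(paste0(s1, s2), "")[[1]])
  sm <- matrix(-1, length(letters_all), length(letters_all),
               dimnames = list(letters_all, letters_all))
  diag(sm) <- 1
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::BString(s1), Biostrings::BString(s2), type = "global",
    substitutionMatrix = sm, gapOpening = 10, gapExtension = 0.5)
  aln_len <- nchar(as.character(Biostrings::alignedPattern(pa)))
  Biostrings::nmatch(pa) / aln_len
}

#' Mean of within-cluster means
#'
#' The cluster-mean reporting rule: average member scores within each
#' cluster, then take the unweighted mean across clusters, so heavily
#' represented molecules do not dominate the headline number.
#'
#' @param scores named numeric vector, member id -> value.
#' @param clusters `ClusterAssignment` covering every scored member.
#' @return numeric scalar.
#' @export
clustered_mean <- function(scores, clusters) {
  cl <- clusters$membership[names(scores)]
  if (anyNA(cl)) stop("scored member(s) missing from cluster assignment: ",
                      paste(names(scores)[is.na(cl)], collapse = ", "))
  mean(tapply(as.numeric(scores), cl, mean))
}
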