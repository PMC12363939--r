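#' Construct an atom-level structure table
#'
#' `atom_table()` builds the shared atom-level representation that every
#' transform in the package reads and returns: one row per atom plus a bond
#' table. Atom identity is a stable surrogate integer (`atom_uid`) assigned at
#' ingestion and never reused, so transforms may delete or reorder atoms
#' without invalidating references held elsewhere (bonds, derived features).
#'
#' @param atoms data.frame with columns `atom_uid` (integer, unique),
#'   `chain_id`, `entity_id`, `res_index` (1-based, following label_seq_id),
#'   `comp_id`, `atom_name`, `element`, `altloc` (single character, "" when
#'   absent), `occupancy` in \[0,1\], `formal_charge` (integer), `x`, `y`, `z`
#'   (angstroms, `NA` when unresolved) and `is_resolved` (logical).
#' @param bonds data.frame with columns `atom_a`, `atom_b` (atom_uids),
#'   `order` (one of `"single"`, `"double"`, `"triple"`, `"aromatic"`) and
#'   `provenance` (one of `"intra_component"`, `"struct_conn"`, `"inferred"`).
#' @return An object of class `AtomTable`.
#' @export
atom_table <- function(atoms = empty_atoms(), bonds = empty_bonds()) {
  obj <- structure(list(atoms = as.data.frame(atoms, stringsAsFactors = FALSE),
                        bonds = as.data.frame(bonds, stringsAsFactors = FALSE)),
                   class = "AtomTable")
  validate_atom_table(obj)
  obj
}

#' @rdname atom_table
#' @export
empty_atoms <- function() {
  data.frame(atom_uid = integer(), chain_id = character(),
             entity_id = integer(), res_index = integer(),
             comp_id = character(), atom_name = character(),
             element = character(), altloc = character(),
             occupancy = numeric(), formal_charge = integer(),
             x = numeric(), y = numeric(), z = numeric(),
             is_resolved = logical(), stringsAsFactors = FALSE)
}

#' @rdname atom_table
#' @export
empty_bonds <- function() {
  data.frame(atom_a = integer(), atom_b = integer(),
             order = character(), provenance = character(),
             stringsAsFactors = FALSE)
}

BOND_ORDERS <- c("single", "double", "triple", "aromatic")
BOND_PROVENANCE <- c("intra_component", "struct_conn", "inferred")

# extras keys whose values are atom_uid sets and must be scrubbed on deletion
UID_EXTRAS <- c("imputed", "imputed_extended")

#' Validate AtomTable invariants
#'
#' Checks the structural invariants every transform must preserve: unique
#' `atom_uid`s, occupancies in \[0,1\], finite coordinates for resolved atoms,
#' bond endpoints referencing existing atoms, no self-bonds, at most one bond
#' per unordered atom pair, and uniqueness of
#' (chain_id, res_index, atom_name, altloc).
#'
#' @param table an `AtomTable`.
#' @return `table`, invisibly; stops with a message on violation.
#' @export
validate_atom_table <- function(table) {
  stopifnot(inherits(table, "AtomTable"))
  a <- table$atoms
  b <- table$bonds
  need <- names(empty_atoms())
  miss <- setdiff(need, names(a))
  if (length(miss)) stop("atoms missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(a$atom_uid)) stop("duplicate atom_uid values")
  if (nrow(a)) {
    bad_occ <- !is.na(a$occupancy) & (a$occupancy < 0 | a$occupancy > 1)
    if (any(bad_occ)) stop("occupancy outside [0,1] for atom_uid ",
                           paste(a$atom_uid[bad_occ], collapse = ", "))
    res <- a$is_resolved
    bad_xyz <- res & (!is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z))
    if (any(bad_xyz)) stop("non-finite coordinates on resolved atom_uid ",
                           paste(a$atom_uid[bad_xyz], collapse = ", "))
    key <- paste(a$chain_id, a$res_index, a$atom_name, a$altloc, sep = "\r")
    if (anyDuplicated(key)) {
      d <- a$atom_uid[duplicated(key)]
      stop("duplicate (chain, res_index, atom_name, altloc) for atom_uid ",
           paste(d, collapse = ", "))
    }
  }
  if (nrow(b)) {
    if (!all(b$order %in% BOND_ORDERS)) stop("invalid bond order")
    if (!all(b$provenance %in% BOND_PROVENANCE)) stop("invalid bond provenance")
    known <- c(b$atom_a, b$atom_b) %in% a$atom_uid
    if (!all(known)) stop("bond references missing atom_uid ",
                          paste(setdiff(c(b$atom_a, b$atom_b), a$atom_uid),
                                collapse = ", "))
    if (any(b$atom_a == b$atom_b)) stop("self-bond present")
    pk <- paste(pmin(b$atom_a, b$atom_b), pmax(b$atom_a, b$atom_b))
    if (anyDuplicated(pk)) stop("duplicate bond for atom pair ",
                                pk[duplicated(pk)][1])
  }
  invisible(table)
}

#' @export
print.AtomTable <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("AtomTable: %d atoms (%d resolved), %d bonds, %d chain(s)\n",
              nrow(a), sum(a$is_resolved), nrow(x$bonds),
              length(unique(a$chain_id))))
  invisible(x)
}

#' Coordinate matrix of an AtomTable
#'
#' @param table an `AtomTable`.
#' @param uids optional atom_uids to extract, in order.
#' @return numeric matrix with one row per atom and columns x, y, z; rownames
#'   are atom_uids.
#' @export
coords_matrix <- function(table, uids = NULL) {
  a <- table$atoms
  if (!is.null(uids)) {
    idx <- match(uids, a$atom_uid)
    if (anyNA(idx)) stop("unknown atom_uid: ",
                         paste(uids[is.na(idx)], collapse = ", "))
    a <- a[idx, , drop = FALSE]
  }
  m <- cbind(x = a$x, y = a$y, z = a$z)
  rownames(m) <- a$atom_uid
  m
}

#' Create a pipeline state
#'
#' A `PipelineState` bundles the atom table with a flat, string-keyed map of
#' derived features (`extras`) and the integer seed governing any stochastic
#' transform in the run. Extras entries that index atoms always do so by
#' `atom_uid`, never by row position.
#'
#' @param table an `AtomTable`.
#' @param extras named list of derived features.
#' @param rng_seed integer seed for the pipeline run.
#' @return An object of class `PipelineState`.
#' @export
pipeline_state <- function(table, extras = list(), rng_seed = 0L) {
  stopifnot(inherits(table, "AtomTable"), is.list(extras))
  structure(list(table = table, extras = extras,
                 rng_seed = as.integer(rng_seed), log = list()),
            class = "PipelineState")
}

#' @export
print.PipelineState <- function(x, ...) {
  cat("PipelineState (seed ", x$rng_seed, ")\n", sep = "")
  print(x$table)
  if (length(x$extras))
    cat("extras:", paste(names(x$extras), collapse = ", "), "\n")
  invisible(x)
}

#' Delete atoms from a pipeline state
#'
#' Removes the named atoms together with every bond incident to them.
#' Remaining `atom_uid`s are unchanged (identity is stable, not positional).
#' Extras entries that carry a `uids` attribute or are integer vectors of
#' atom_uids have references to deleted atoms dropped, with a log entry.
#'
#' @param state a `PipelineState`.
#' @param uids integer vector of atom_uids to delete (may be empty).
#' @return The updated `PipelineState`.
#' @export
delete_atoms <- function(state, uids) {
  stopifnot(inherits(state, "PipelineState"))
  uids <- unique(as.integer(uids))
  if (!length(uids)) return(state)
  a <- state$table$atoms
  unknown <- setdiff(uids, a$atom_uid)
  if (length(unknown)) stop("delete_atoms: unknown atom_uid ",
                            paste(unknown, collapse = ", "))
  b <- state$table$bonds
  keep_b <- !(b$atom_a %in% uids | b$atom_b %in% uids)
  state$table$atoms <- a[!(a$atom_uid %in% uids), , drop = FALSE]
  state$table$bonds <- b[keep_b, , drop = FALSE]
  # scrub uid references from the extras entries that hold atom_uid sets
  dropped <- character()
  for (k in intersect(names(state$extras), UID_EXTRAS)) {
    v <- state$extras[[k]]
    if (is.integer(v) && length(v) && any(v %in% uids)) {
      state$extras[[k]] <- v[!(v %in% uids)]
      dropped <- c(dropped, k)
    }
  }
  if (length(dropped))
    state$log <- c(state$log, list(paste0(
      "delete_atoms: dropped references to deleted atoms from extras: ",
      paste(dropped, collapse = ", "))))
  state$log <- c(state$log, list(sprintf(
    "delete_atoms: removed %d atoms, %d bonds", length(uids), sum(!keep_b))))
  validate_atom_table(state$table)
  state
}

#' Fresh atom_uids for appended atoms
#'
#' @param table an `AtomTable`.
#' @param n number of uids needed.
#' @return integer vector of `n` uids greater than any in use.
#' @keywords internal
next_uids <- function(table, n) {
  base <- if (nrow(table$atoms)) max(table$atoms$atom_uid) else 0L
  seq.int(base + 1L, length.out = n)
}

# residue-level grouping key used across modules
residue_key <- function(atoms) paste(atoms$chain_id, atoms$res_index, sep = "\r")
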