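# Transform registry and composable pipelines.
#
# A transform is a named function PipelineState -> PipelineState registered
# together with the extras keys it reads and writes. Pipelines are ordered
# lists of (transform, params) steps, serializable to/from YAML so a run is
# fully described by a declarative config plus one integer seed.

.transform_registry <- new.env(parent = emptyenv())

#' Register a pipeline transform
#'
#' @param name transform name used in pipeline configs.
#' @param fn function(state, ...) returning a `PipelineState`.
#' @param reads,writes character vectors of extras keys the transform reads
#'   and writes; writing a key another step already wrote is a configuration
#'   error (collisions are never silently overwritten).
#' @return `name`, invisibly.
#' @export
register_transform <- function(name, fn, reads = character(), writes = character()) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, list(fn = fn, reads = reads, writes = writes),
         envir = .transform_registry)
  invisible(name)
}

#' List registered transform names
#' @return character vector.
#' @export
list_transforms <- function() sort(ls(.transform_registry))

get_transform <- function(name) {
  if (!exists(name, envir = .transform_registry, inherits = FALSE))
    stop("unknown transform '", name, "'; known: ",
         paste(list_transforms(), collapse = ", "))
  get(name, envir = .transform_registry, inherits = FALSE)
}

#' Compose named transforms into a pipeline
#'
#' @param transforms list of steps; each step is either a transform name or a
#'   list with elements `transform` (name) and optional `params` (named list).
#' @return An object of class `Pipeline` whose application is the
#'   left-to-right composition of its steps.
#' @export
compose_pipeline <- function(transforms = list()) {
  steps <- lapply(transforms, function(s) {
    if (is.character(s)) s <- list(transform = s, params = list())
    if (is.null(s$params)) s$params <- list()
    get_transform(s$transform)  # errors early on unknown names
    s[c("transform", "params")]
  })
  # extras write collisions are a configuration error, not a precedence rule
  written <- character()
  for (s in steps) {
    w <- get_transform(s$transform)$writes
    clash <- intersect(w, written)
    if (length(clash))
      stop("extras key collision: '", paste(clash, collapse = "', '"),
           "' written by more than one step (offender: ", s$transform, ")")
    written <- c(written, w)
  }
  structure(list(steps = steps), class = "Pipeline")
}

#' @export
print.Pipeline <- function(x, ...) {
  cat("Pipeline with", length(x$steps), "step(s):",
      paste(vapply(x$steps, `[[`, "", "transform"), collapse = " -> "), "\n")
  invisible(x)
}

#' Serialize / parse a pipeline config
#'
#' The YAML form is a list of `{transform, params}` entries; round-tripping
#' through `serialize_pipeline()` and `parse_pipeline()` yields a pipeline
#' with an identical step list.
#'
#' @param pipeline a `Pipeline`.
#' @param text YAML text as produced by `serialize_pipeline()`.
#' @return `serialize_pipeline()`: a YAML string; `parse_pipeline()`: a
#'   `Pipeline`.
#' @export
serialize_pipeline <- function(pipeline) {
  stopifnot(inherits(pipeline, "Pipeline"))
  yaml::as.yaml(lapply(pipeline$steps, function(s)
    list(transform = s$transform, params = s$params)))
}

#' @rdname serialize_pipeline
#' @export
parse_pipeline <- function(text) {
  compose_pipeline(yaml::yaml.load(text))
}

#' Apply a pipeline to a state
#'
#' Steps run left to right; the table is validated after every step, and a
#' per-transform log entry records atom counts before/after. With identical
#' input and `rng_seed` the output is identical across runs: every stochastic
#' transform derives its stream from `(rng_seed, transform name)` via
#' [derive_seed()].
#'
#' @param pipeline a `Pipeline`.
#' @param state a `PipelineState` satisfying the AtomTable invariants.
#' @return The transformed `PipelineState`.
#' @export
apply_pipeline <- function(pipeline, state) {
  stopifnot(inherits(pipeline, "Pipeline"), inherits(state, "PipelineState"))
  validate_atom_table(state$table)
  for (s in pipeline$steps) {
    tr <- get_transform(s$transform)
    n0 <- nrow(state$table$atoms)
    state <- tryCatch(
      do.call(tr$fn, c(list(state), s$params)),
      error = function(e) stop("pipeline stage '", s$transform, "' failed: ",
                               conditionMessage(e), call. = FALSE))
    if (!inherits(state, "PipelineState"))
      stop("pipeline stage '", s$transform, "' did not return a PipelineState")
    validate_atom_table(state$table)
    state$log <- c(state$log, list(sprintf("%s: %d -> %d atoms",
                                           s$transform, n0,
                                           nrow(state$table$atoms))))
  }
  state
}

#' Derive a reproducible sub-seed for a named transform
#'
#' Hashes `(seed, name)` into a positive integer below 2^31 so each transform
#' in a run draws from its own stream while the whole run is governed by one
#' pipeline seed.
#'
#' @param seed integer pipeline seed.
#' @param name transform name.
#' @return integer sub-seed.
#' @export
derive_seed <- function(seed, name) {
  h <- as.double(seed) %% 2147483647
  for (cp in utf8ToInt(name)) h <- (h * 131 + cp) %% 2147483647
  as.integer(h %% 2147483629 + 1)
}
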