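#' Configuration for the fragviz pipeline
#'
#' Collects every tunable of the two-stage layout in one list. All values have
#' units of the dissimilarity matrix `D` unless stated otherwise.
#'
#' @param fr_iterations Fruchterman-Reingold iterations per component.
#'   Components in fragmented biological networks are small (tens of
#'   vertices), so a generous budget is cheap.
#' @param mds_max_iter Maximum SMACOF majorization iterations.
#' @param mds_tol Relative stress-change convergence tolerance for SMACOF.
#' @param mds_init SMACOF initialization: `"random"` (seeded points in the
#'   unit disk) or `"torgerson"` (classical scaling start).
#' @param anneal_sweeps Number of rotation-annealing sweeps over all
#'   components.
#' @param anneal_t0 Initial annealing temperature; `0` gives a purely greedy
#'   rotation phase.
#' @param anneal_decay Multiplicative temperature decay per sweep, in (0, 1).
#' @param step_c Proportionality constant converting per-component net force
#'   into a translation step in the exact simulation.
#' @param step_phi Proportionality constant converting torque per moment of
#'   inertia into a rotation step (radians), used by both engines.
#' @param force_tol Exact-simulation convergence threshold on the largest
#'   per-vertex force magnitude.
#' @param max_iterations Exact-simulation iteration cap.
#'
#' @return A named list of class `fragviz_config`.
#' @export
#' @examples
#' cfg <- fragviz_config(anneal_sweeps = 20)
#' cfg$anneal_sweeps
fragviz_config <- function(fr_iterations = 500,
                           mds_max_iter = 300,
                           mds_tol = 1e-8,
                           mds_init = c("random", "torgerson"),
                           anneal_sweeps = 50,
                           anneal_t0 = 1,
                           anneal_decay = 0.9,
                           step_c = 0.1,
                           step_phi = 0.1,
                           force_tol = 1e-4,
                           max_iterations = 2000) {
  mds_init <- match.arg(mds_init)
  stopifnot(
    fr_iterations >= 1, mds_max_iter >= 1, mds_tol > 0,
    anneal_sweeps >= 1, anneal_t0 >= 0,
    anneal_decay > 0, anneal_decay < 1,
    step_c > 0, step_phi > 0, force_tol > 0, max_iterations >= 1
  )
  structure(
    list(
      fr_iterations = as.integer(fr_iterations),
      mds_max_iter = as.integer(mds_max_iter),
      mds_tol = mds_tol,
      mds_init = mds_init,
      anneal_sweeps = as.integer(anneal_sweeps),
      anneal_t0 = anneal_t0,
      anneal_decay = anneal_decay,
      step_c = step_c,
      step_phi = step_phi,
      force_tol = force_tol,
      max_iterations = as.integer(max_iterations)
    ),
    class = "fragviz_config"
  )
}

#' Read a pipeline configuration from a file
#'
#' Accepts either a JSON object or a plain `key=value` file (one pair per
#' line, `#` comments allowed); keys match the arguments of
#' [fragviz_config()], with dots accepted in place of underscores
#' (`mds.tol` == `mds_tol`). Unknown keys are an error.
#'
#' @param path Path to the configuration file.
#' @return A `fragviz_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  txt <- readLines(path, warn = FALSE)
  vals <- if (any(grepl("^\\s*\\{", txt))) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      abort("jsonlite is required to read JSON config files")
    }
    jsonlite::fromJSON(paste(txt, collapse = "\n"))
  } else {
    txt <- trimws(sub("#.*$", "", txt))
    txt <- txt[nzchar(txt)]
    kv <- strsplit(txt, "=", fixed = TRUE)
    bad <- lengths(kv) != 2L
    if (any(bad)) abort(paste0("malformed config line: ", txt[bad][1]))
    setNames(
      lapply(kv, function(p) type.convert(trimws(p[2]), as.is = TRUE)),
      vapply(kv, function(p) trimws(p[1]), "")
    )
  }
  names(vals) <- gsub(".", "_", names(vals), fixed = TRUE)
  known <- names(formals(fragviz_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(fragviz_config, vals)
}

# seed_k = seed for component k; identity at k = 1 so a single-component
# pipeline consumes the user's seed directly.
derive_seed <- function(seed, k) {
  (as.numeric(seed) %% 2147483647 + (k - 1) * 1103515245) %% 2147483647
}
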