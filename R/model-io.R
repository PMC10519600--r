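#' Read a model specification file
#'
#' Models are stored as structured text (YAML) with sections `states`,
#' `odes`, `inputs`, `observables`, `errors`, `parameters`, `initials`, and
#' optionally `cell_types`. Expressions are plain strings; parameters are
#' maps with `value` (estimation scale) and `log` (default `TRUE`). The
#' `errors` section gives a default standard deviation per observable, used
#' by data simulation when no sigma is supplied. When `cell_types` (fields
#' `n_cell_types`, `reference`, `specific`) is present the replicated model is built as
#' well.
#'
#' @param path file path.
#' @return list with `model` (an [ode_model()]), `multicell` (a
#'   [replicate_model()] object or `NULL`), and `errors` (named numeric or
#'   `NULL`).
#' @examples
#' \dontrun{
#' spec <- read_model_file("decay.yaml")
#' spec$multicell
#' }
#' @export
read_model_file <- function(path) {
  raw <- yaml::read_yaml(path)
  for (sec in c("states", "odes", "observables", "parameters", "initials")) {
    if (is.null(raw[[sec]])) {
      stop("model file missing section '", sec, "': ", path, call. = FALSE)
    }
  }
  pn <- names(raw$parameters)
  pv <- vapply(raw$parameters, function(p) {
    if (is.list(p)) as.numeric(p$value %||% 0) else as.numeric(p)
  }, numeric(1))
  plog <- vapply(raw$parameters, function(p) {
    if (is.list(p)) isTRUE(p$log %||% TRUE) else TRUE
  }, logical(1))
  model <- ode_model(
    states = raw$states,
    odes = raw$odes,
    observables = raw$observables,
    parameters = stats::setNames(pv, pn),
    initials = raw$initials,
    inputs = raw$inputs %||% list(),
    log_scale = stats::setNames(plog, pn),
    condition_vars = as.character(raw$condition_vars %||% character())
  )
  multicell <- NULL
  if (!is.null(raw$cell_types)) {
    ct <- raw$cell_types
    n_ct <- ct$n_cell_types %||% ct$n
    if (is.null(n_ct) || is.null(ct$specific)) {
      stop("cell_types section needs fields 'n_cell_types' and 'specific'",
           call. = FALSE)
    }
    multicell <- replicate_model(model, n = n_ct,
                                 specific = as.character(ct$specific),
                                 reference = ct$reference %||% 1L)
  }
  errors <- if (!is.null(raw$errors)) {
    vapply(raw$errors, as.numeric, numeric(1))
  }
  list(model = model, multicell = multicell, errors = errors)
}
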