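#' Read and write experiment tables
#'
#' Experiment data are kept in long format, one measurement per row, with
#' columns `time`, `observable`, `value`, `sigma` (the per-point standard
#' deviation), `cell_type`, and an optional `condition` column identifying
#' the experimental condition (e.g. a dose) when the model uses condition
#' constants. Files are tab-separated text with a header.
#'
#' @param path file path.
#' @return a tibble.
#' @export
read_experiment_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (nrow(df) == 0L) stop("experiment table is empty: ", path, call. = FALSE)
  validate_experiment_table(tibble::as_tibble(df))
}

#' @rdname read_experiment_table
#' @param data an experiment table.
#' @export
write_experiment_table <- function(data, path) {
  data <- validate_experiment_table(data)
  utils::write.table(data, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_experiment_table
#' @param mcm optionally, a [replicate_model()] object to validate
#'   observables and cell-type indices against.
#' @export
validate_experiment_table <- function(data, mcm = NULL) {
  required <- c("time", "observable", "value", "sigma", "cell_type")
  missing <- setdiff(required, names(data))
  if (length(missing)) {
    stop("experiment table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"condition" %in% names(data)) data$condition <- "1"
  data$condition <- as.character(data$condition)
  data$cell_type <- as.integer(data$cell_type)
  if (any(!is.finite(data$sigma)) || any(data$sigma <= 0)) {
    stop("all `sigma` values must be finite and > 0", call. = FALSE)
  }
  if (any(data$time < 0)) stop("negative `time` values", call. = FALSE)
  if (!is.null(mcm)) {
    bad <- setdiff(unique(data$observable), names(mcm$model$observables))
    if (length(bad)) {
      stop("observable(s) not defined in model: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (any(data$cell_type < 1L | data$cell_type > mcm$n)) {
      stop("cell_type indices outside 1..n", call. = FALSE)
    }
  }
  tibble::as_tibble(data)
}
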