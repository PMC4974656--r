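# Dataset container: one directory of plain-text files, chosen for
# inspectability and diff-ability.  Layout:
#   meta.json      imaging rate, seed, schema version
#   raw.csv        frames x ROIs raw fluorescence
#   neuropil.csv   frames x ROIs neuropil fluorescence
#   running.csv    running indicator per frame
#   cells.csv      cell geometry table
#   stimulus.csv   stimulus log (onset_s, kx, ky, ...)

DATASET_SCHEMA <- 1L
DATASET_FILES <- c("meta.json", "raw.csv", "neuropil.csv", "running.csv",
                   "cells.csv", "stimulus.csv")

#' Write / read a dataset container
#'
#' Serializes the pipeline's input data (raw and neuropil traces, running
#' state, cell table, stimulus log) to a directory of plain-text files
#' and reads it back losslessly (floats survive at full precision).
#'
#' @param dataset A `synthetic_dataset`, or any list with `raw`,
#'   `neuropil`, `running`, `cells`, `stimulus`, `imaging_rate_hz`.
#' @param path Directory to create/read.
#' @export
write_dataset <- function(dataset, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    schema = DATASET_SCHEMA,
    imaging_rate_hz = dataset$imaging_rate_hz,
    seed = if (is.null(dataset$seed)) NA else dataset$seed,
    n_frames = nrow(dataset$raw),
    n_cells = ncol(dataset$raw)
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  write_matrix_csv(dataset$raw, file.path(path, "raw.csv"))
  write_matrix_csv(dataset$neuropil, file.path(path, "neuropil.csv"))
  write_matrix_csv(matrix(dataset$running, ncol = 1),
                   file.path(path, "running.csv"))
  utils::write.csv(as.data.frame(dataset$cells),
                   file.path(path, "cells.csv"), row.names = FALSE)
  write_stimulus_log(dataset$stimulus, file.path(path, "stimulus.csv"))
  invisible(path)
}

#' @rdname write_dataset
#' @param screen,sf_max_cpd Grid parameters used to re-annotate the
#'   stimulus log.
#' @return `read_dataset()` returns a list mirroring the structure of a
#'   [simulate_dataset()] result (without ground truth), including the
#'   rebuilt `design`.
#' @export
read_dataset <- function(path, screen = screen_geometry(),
                         sf_max_cpd = 0.15) {
  missing <- DATASET_FILES[!file.exists(file.path(path, DATASET_FILES))]
  if (length(missing)) {
    abort(paste("dataset container is missing:",
                paste(missing, collapse = ", ")))
  }
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  raw <- read_matrix_csv(file.path(path, "raw.csv"))
  neuropil <- read_matrix_csv(file.path(path, "neuropil.csv"))
  running <- as.numeric(read_matrix_csv(file.path(path, "running.csv")))
  cells <- as_tibble(utils::read.csv(file.path(path, "cells.csv")))
  stimulus <- read_stimulus_log(file.path(path, "stimulus.csv"), screen,
                                sf_max_cpd)
  if (nrow(raw) != meta$n_frames || ncol(raw) != meta$n_cells) {
    abort("dataset container is corrupt: trace dimensions disagree with meta")
  }
  design <- build_design(stimulus, meta$imaging_rate_hz,
                         n_frames = meta$n_frames)
  list(raw = raw, neuropil = neuropil, running = running, cells = cells,
       stimulus = stimulus, design = design,
       imaging_rate_hz = meta$imaging_rate_hz, seed = meta$seed)
}

# full-precision text round trip for numeric matrices
write_matrix_csv <- function(m, path) {
  m <- as.matrix(m)
  txt <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
  utils::write.table(txt, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

read_matrix_csv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE,
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  m
}
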