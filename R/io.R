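#' @include AllClasses.R
NULL

#' Write a voltage trace to CSV with a JSON sidecar
#'
#' The trace goes to \code{<path>} as CSV with header
#' \code{time_ms,voltage_mV,current_pA}; the metadata (neuron and bird ids,
#' dt, stimulus protocol, provenance) goes to \code{<path but
#' .meta.json>}.
#'
#' @param trace a VoltageTrace.
#' @param path output CSV path.
#' @return Invisibly, the sidecar path.
#' @export
writeTraceCsv <- function(trace, path) {
  stopifnot(is(trace, "VoltageTrace"))
  df <- data.frame(time_ms = trace@timeMs, voltage_mV = trace@voltageMv,
                   current_pA = trace@currentPa)
  write.csv(df, path, row.names = FALSE)
  pr <- trace@metadata$protocol
  meta <- list(
    neuron_id = trace@metadata$neuron_id,
    bird_id = trace@metadata$bird_id,
    dt_ms = trace@dtMs,
    protocol = if (!is.null(pr)) list(
      kind = pr@kind, amplitude_pA = pr@amplitude, pre_ms = pr@preMs,
      stim_ms = pr@stimMs, post_ms = pr@postMs,
      seed = if (is.na(pr@seed)) NULL else pr@seed,
      holding_mV = pr@holdingMv),
    provenance = trace@metadata$provenance
  )
  side <- sub("\\.csv$", "", path)
  side <- paste0(side, ".meta.json")
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(side)
}

#' Read a voltage trace from CSV (+ JSON sidecar)
#'
#' @param path CSV path written by \code{\link{writeTraceCsv}} (or matching
#'   its format).
#' @return A VoltageTrace; protocol metadata restored from the sidecar when
#'   present.
#' @export
readTraceCsv <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("time_ms", "voltage_mV", "current_pA") %in% names(df)))
  dt <- if (nrow(df) >= 2) df$time_ms[2] - df$time_ms[1] else 1
  md <- list(provenance = "external")
  side <- paste0(sub("\\.csv$", "", path), ".meta.json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    md$neuron_id <- meta$neuron_id
    md$bird_id <- meta$bird_id
    md$provenance <- meta$provenance %||% "external"
    if (!is.null(meta$protocol)) {
      pz <- meta$protocol
      md$protocol <- new("StimulusProtocol",
        kind = pz$kind %||% "step", amplitude = pz$amplitude_pA %||% 0,
        preMs = pz$pre_ms %||% 200, stimMs = pz$stim_ms %||% 200,
        postMs = pz$post_ms %||% 200, dtMs = meta$dt_ms %||% dt,
        holdingMv = pz$holding_mV %||% -70,
        seed = as.integer(pz$seed %||% NA))
    }
  }
  new("VoltageTrace", timeMs = df$time_ms, voltageMv = df$voltage_mV,
      currentPa = df$current_pA, dtMs = dt, metadata = md)
}

#' Write / read a fitted-conductance table
#'
#' CSV with columns neuron_id, bird_id, gNa, gK, gSK, gh, gCaT, error,
#' disregarded_count.
#'
#' @param fits data.frame of fits.
#' @param path CSV path.
#' @return \code{writeFitsCsv}: invisibly the path; \code{readFitsCsv}: the
#'   data.frame.
#' @export
writeFitsCsv <- function(fits, path) {
  need <- c("neuron_id", "bird_id", conductanceNames())
  stopifnot(all(need %in% names(fits)))
  write.csv(fits, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFitsCsv
#' @export
readFitsCsv <- function(path) {
  fits <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("neuron_id", "bird_id", conductanceNames())
  stopifnot(all(need %in% names(fits)))
  fits
}

#' Write / read a song-similarity matrix
#'
#' Square CSV with bird ids as header row and first column.
#'
#' @param similarity square numeric matrix with bird-id dimnames.
#' @param path CSV path.
#' @return \code{writeSimilarityCsv}: invisibly the path;
#'   \code{readSimilarityCsv}: the matrix.
#' @export
writeSimilarityCsv <- function(similarity, path) {
  stopifnot(is.matrix(similarity), nrow(similarity) == ncol(similarity))
  df <- data.frame(bird_id = rownames(similarity), similarity,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSimilarityCsv
#' @export
readSimilarityCsv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
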