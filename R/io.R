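# Delimited-text I/O. All files are plain text: signals one sample per line
# (optionally a time column), matrices and bases as whitespace-delimited
# numeric rows behind a single '#'-prefixed header line carrying the
# metadata needed to rebuild the object.

#' Read a signal from delimited text
#'
#' Accepts one-column files (amplitude per line) or two-column files
#' (time, amplitude); the sampling rate is supplied by the caller, never
#' inferred from a time column.
#'
#' @param path File path. Lines starting with `#` are skipped.
#' @return Numeric vector of samples.
#' @export
read_signal <- function(path) {
  tab <- read.table(path, header = FALSE, comment.char = "#")
  if (ncol(tab) == 1L) as.numeric(tab[[1L]])
  else if (ncol(tab) == 2L) as.numeric(tab[[2L]])
  else stop("signal files must have one (amplitude) or two (time, amplitude) columns",
            call. = FALSE)
}

#' Write a signal as one sample per line
#'
#' @param samples Numeric vector or `cs_frame`.
#' @param path Output file path.
#' @export
write_signal <- function(samples, path) {
  write.table(frame_samples(samples), path, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a measurement matrix as delimited text
#'
#' The header line records M, N and the seed, so the file round-trips
#' through [read_measurement_matrix()].
#'
#' @param phi A `cs_measurement_matrix`.
#' @param path Output file path.
#' @export
write_measurement_matrix <- function(phi, path) {
  stopifnot(inherits(phi, "cs_measurement_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# M %d N %d seed %d", phi$M, phi$N, phi$seed), con)
  write.table(phi$entries, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a measurement matrix written by [write_measurement_matrix()]
#'
#' @param path File path.
#' @return A `cs_measurement_matrix`.
#' @export
read_measurement_matrix <- function(path) {
  header <- readLines(path, n = 1L)
  fields <- strsplit(sub("^#\\s*", "", header), "\\s+")[[1L]]
  meta <- as.integer(fields[c(2L, 4L, 6L)])
  entries <- as.matrix(read.table(path, header = FALSE, skip = 1L))
  dimnames(entries) <- NULL
  storage.mode(entries) <- "double"
  if (!all(entries %in% c(-1, 1)) ||
      nrow(entries) != meta[1L] || ncol(entries) != meta[2L]) {
    stop("file does not contain a valid +/-1 measurement matrix", call. = FALSE)
  }
  structure(
    list(entries = entries, M = meta[1L], N = meta[2L], seed = meta[3L]),
    class = "cs_measurement_matrix"
  )
}

#' Write a basis matrix as delimited text
#'
#' @param psi A `cs_basis`.
#' @param path Output file path.
#' @export
write_basis <- function(psi, path) {
  stopifnot(inherits(psi, "cs_basis"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind %s N %d levels %s", psi$kind, nrow(psi$columns),
                     ifelse(is.na(psi$levels), "NA", psi$levels)), con)
  write.table(psi$columns, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a sweep result table
#'
#' Tab-delimited with a header row; reread with [read_sweep_result()].
#'
#' @param result data.frame from [cs_sweep()] or [run_cell()].
#' @param path Output file path.
#' @export
write_sweep_result <- function(result, path) {
  write.table(result, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sweep_result
#' @export
read_sweep_result <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
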