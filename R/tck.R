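# MRtrix .tck streamline file I/O.
#
# Format: a text header starting with the magic line "mrtrix tracks",
# key: value lines including "datatype:" and "file: . <offset>", terminated
# by a line reading "END"; then, at <offset> bytes from the start of the
# file, 32-bit float coordinate triplets, with an all-NaN triplet separating
# streamlines and an all-Inf triplet terminating the stream.

#' Read an MRtrix .tck streamline file
#'
#' @param path Path to a `.tck` file.
#' @param area_a,area_b,subject_id,session Optional bundle metadata attached
#'   to the result.
#' @return A `saf_bundle`.
#' @export
read_tck <- function(path, area_a = NA_character_, area_b = NA_character_,
                     subject_id = NA_character_, session = NA_character_) {
  fmt_error <- function(msg, offset) {
    abort(paste0("malformed TCK file '", path, "': ", msg,
                 " (byte offset ", offset, ")"),
          class = "safconn_tck_format")
  }
  size <- file.size(path)
  if (is.na(size)) fmt_error("file not readable", 0L)
  raw <- readBin(path, "raw", n = size)
  if (length(raw) < 13L ||
      !identical(rawToChar(raw[1:13]), "mrtrix tracks")) {
    fmt_error("missing magic line", 0L)
  }
  # locate the END line terminating the header
  nl <- which(raw == as.raw(10L))
  header_end <- NA_integer_
  line_start <- 1L
  header_lines <- character()
  for (pos in nl) {
    line <- rawToChar(raw[line_start:(pos - 1L)])
    if (identical(line, "END")) { header_end <- pos; break }
    header_lines <- c(header_lines, line)
    line_start <- pos + 1L
  }
  if (is.na(header_end)) fmt_error("header not terminated by END", length(raw))
  header_lines <- header_lines[-1L]  # drop magic line
  fields <- strsplit(header_lines, ":", fixed = TRUE)
  keys <- trimws(vapply(fields, `[`, character(1), 1L))
  vals <- trimws(vapply(fields, function(f) paste(f[-1], collapse = ":"),
                        character(1)))
  datatype <- vals[match("datatype", keys)]
  if (is.na(datatype)) fmt_error("missing datatype field", header_end)
  endian <- switch(datatype, Float32LE = "little", Float32BE = "big", NA)
  if (is.na(endian)) fmt_error(paste0("unsupported datatype ", datatype), header_end)
  file_field <- vals[match("file", keys)]
  if (is.na(file_field)) fmt_error("missing file field", header_end)
  parts <- strsplit(file_field, "[[:space:]]+")[[1]]
  offset <- suppressWarnings(as.integer(parts[length(parts)]))
  if (is.na(offset) || offset < header_end || offset > length(raw)) {
    fmt_error("invalid data offset", header_end)
  }
  n_bytes <- length(raw) - offset
  if (n_bytes < 12L || n_bytes %% 12L != 0L) {
    fmt_error("truncated coordinate data", offset)
  }
  vals32 <- readBin(raw[(offset + 1L):length(raw)], "numeric",
                    n = n_bytes / 4L, size = 4L, endian = endian)
  pts <- matrix(vals32, ncol = 3L, byrow = TRUE)
  if (!all(is.infinite(pts[nrow(pts), ]))) {
    fmt_error("missing Inf terminator", offset + (nrow(pts) - 1L) * 12L)
  }
  pts <- pts[seq_len(nrow(pts) - 1L), , drop = FALSE]
  streamlines <- list()
  if (nrow(pts) > 0L) {
    is_sep <- rowSums(is.na(pts)) == 3L
    group <- cumsum(c(TRUE, is_sep[-length(is_sep)]))
    for (g in split.data.frame(pts, group)) {
      g <- g[rowSums(is.na(g)) == 0L, , drop = FALSE]
      if (nrow(g) > 0L) {
        streamlines[[length(streamlines) + 1L]] <- unname(as.matrix(g))
      }
    }
  }
  bundle(streamlines, area_a = area_a, area_b = area_b,
         subject_id = subject_id, session = session)
}

#' Write a bundle to an MRtrix .tck file
#'
#' Coordinates are stored as little-endian 32-bit floats, so a round trip
#' preserves streamline counts exactly and coordinates to single precision.
#'
#' @param b A `saf_bundle` (may be empty).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tck <- function(b, path) {
  n <- length(b$streamlines)
  header_for <- function(offset) {
    paste0("mrtrix tracks\n",
           "datatype: Float32LE\n",
           "count: ", n, "\n",
           "safconn_connection: ",
           if (is.na(b$area_a)) "none" else paste0(b$area_a, "-", b$area_b), "\n",
           "file: . ", offset, "\n",
           "END\n")
  }
  # fixed-point iteration: the offset value appears inside the header
  offset <- nchar(header_for(0L), type = "bytes")
  repeat {
    new_offset <- nchar(header_for(offset), type = "bytes")
    if (new_offset == offset) break
    offset <- new_offset
  }
  blocks <- lapply(b$streamlines, function(s) rbind(s, c(NaN, NaN, NaN)))
  data <- do.call(rbind, c(blocks, list(matrix(c(Inf, Inf, Inf), 1L))))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header_for(offset), con, eos = NULL)
  writeBin(as.numeric(t(data)), con, size = 4L, endian = "little")
  invisible(path)
}
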