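# Tractogram container and MRtrix track-file (.tck) I/O.
#
# A tractogram is a list of streamlines; each streamline is an n x 3 numeric
# matrix of points in real-world millimetres (n >= 2). The .tck layout is the
# standard MRtrix one: a text header ("mrtrix tracks" magic, key: value lines,
# terminated by END), then float32 triplets with NaN-triplet separators
# between streamlines and a single Inf-triplet terminator.

#' Construct a tractogram
#'
#' @param streamlines list of numeric matrices, each `n x 3` with `n >= 2`,
#'   coordinates in mm.
#' @return object of class `tractogram`.
#' @export
tractogram <- function(streamlines = list()) {
  streamlines <- lapply(streamlines, function(s) {
    s <- as.matrix(s)
    storage.mode(s) <- "double"
    if (ncol(s) != 3) stop("each streamline must have 3 columns (x, y, z)")
    if (nrow(s) < 2) stop("each streamline must have at least 2 points")
    if (!all(is.finite(s))) stop("streamline coordinates must be finite")
    dimnames(s) <- NULL
    s
  })
  structure(list(streamlines = streamlines, count = length(streamlines)),
            class = "tractogram")
}

#' @exportS3Method
print.tractogram <- function(x, ...) {
  npts <- vapply(x$streamlines, nrow, integer(1))
  cat("tractogram:", x$count, "streamlines")
  if (x$count > 0) cat(" (", min(npts), "-", max(npts), " points each)", sep = "")
  cat("\n")
  invisible(x)
}

#' @exportS3Method
length.tractogram <- function(x) x$count

#' Terminal points of every streamline
#'
#' @param trk a `tractogram`.
#' @return `2*count x 3` matrix: rows `2i-1` and `2i` are the first and last
#'   point of streamline `i`.
#' @export
streamline_endpoints <- function(trk) {
  stopifnot(inherits(trk, "tractogram"))
  if (trk$count == 0) return(matrix(numeric(0), ncol = 3))
  nr <- vapply(trk$streamlines, nrow, integer(1))
  out <- matrix(NA_real_, nrow = 2L * trk$count, ncol = 3)
  odd <- seq(1L, 2L * trk$count, by = 2L)
  if (all(nr == nr[1])) {
    # equal-length fast path: one flat copy, then strided indexing
    flat <- matrix(unlist(trk$streamlines, use.names = FALSE), nrow = nr[1])
    cols <- 3L * (seq_len(trk$count) - 1L)
    for (k in 1:3) {
      out[odd, k] <- flat[1L, cols + k]
      out[odd + 1L, k] <- flat[nr[1], cols + k]
    }
  } else {
    firsts <- vapply(trk$streamlines, function(s) s[1L, ], numeric(3))
    lasts <- vapply(trk$streamlines, function(s) s[nrow(s), ], numeric(3))
    out[odd, ] <- t(firsts)
    out[odd + 1L, ] <- t(lasts)
  }
  out
}

#' Write a tractogram to an MRtrix track file
#'
#' @param trk a `tractogram`.
#' @param path output path (conventionally `.tck`).
#' @return `path`, invisibly.
#' @export
write_track_file <- function(trk, path) {
  stopifnot(inherits(trk, "tractogram"))
  header_body <- paste0(
    "mrtrix tracks\n",
    "datatype: Float32LE\n",
    "count: ", trk$count, "\n"
  )
  # the "file: . <offset>" line length feeds back into the offset; pinning
  # the offset field to a fixed 10-char width makes the arithmetic closed
  offset <- nchar(header_body, type = "bytes") +
    nchar("file: . ") + 10L + 1L + nchar("END\n")
  file_line <- sprintf("file: . %-10d\n", offset)
  header <- paste0(header_body, file_line, "END\n")
  stopifnot(nchar(header, type = "bytes") == offset)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  for (s in trk$streamlines) {
    writeBin(as.vector(t(s)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRtrix track file
#'
#' Parses the text header (datatype, count, file offset) and the float32
#' triplet stream; streamlines are separated by NaN triplets and the stream is
#' terminated by an Inf triplet. Malformed headers, unsupported datatypes and
#' truncated triplet streams raise errors naming the offending field.
#'
#' @param path path to a `.tck` file.
#' @return a `tractogram`.
#' @export
read_track_file <- function(path) {
  if (!file.exists(path)) stop("track file does not exist: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!identical(magic, "mrtrix tracks")) {
    stop("malformed track header: missing 'mrtrix tracks' magic line")
  }
  fields <- list()
  offset <- NA_integer_
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0) stop("malformed track header: no END line")
    if (identical(line, "END")) break
    kv <- regmatches(line, regexec("^([^:]+):\\s*(.*)$", line))[[1]]
    if (length(kv) != 3) stop("malformed track header line: ", line)
    fields[[trimws(kv[2])]] <- trimws(kv[3])
  }
  datatype <- fields[["datatype"]]
  if (is.null(datatype)) stop("malformed track header: missing field 'datatype'")
  endian <- switch(datatype,
    Float32LE = "little", Float32BE = "big",
    stop("unsupported track datatype: ", datatype)
  )
  if (is.null(fields[["file"]])) stop("malformed track header: missing field 'file'")
  offset <- as.integer(sub("^\\.\\s*", "", fields[["file"]]))
  if (is.na(offset)) stop("malformed track header: unparseable 'file' offset")
  seek(con, where = offset, origin = "start")
  nbytes <- file.info(path)$size - offset
  if (nbytes %% 4 != 0) stop("truncated track data: byte count not a multiple of 4")
  vals <- readBin(con, "numeric", n = nbytes / 4, size = 4, endian = endian)
  if (length(vals) %% 3 != 0) stop("truncated track data: stream ends mid-triplet")
  pts <- matrix(vals, ncol = 3, byrow = TRUE)
  is_nan <- rowSums(is.na(pts) & !is.infinite(pts)) > 0
  is_inf <- rowSums(is.infinite(pts)) > 0
  if (!any(is_inf)) stop("truncated track data: missing Inf terminator triplet")
  end <- which(is_inf)[1]
  pts <- pts[seq_len(end - 1L), , drop = FALSE]
  is_nan <- is_nan[seq_len(end - 1L)]
  # split on NaN separators
  grp <- cumsum(is_nan)
  keep <- !is_nan
  streamlines <- list()
  if (any(keep)) {
    idx <- split(which(keep), grp[keep])
    streamlines <- lapply(idx, function(i) pts[i, , drop = FALSE])
    names(streamlines) <- NULL
  }
  trk <- tractogram(streamlines)
  declared <- suppressWarnings(as.integer(fields[["count"]]))
  if (!is.na(declared) && declared != trk$count) {
    stop("track header count (", declared, ") does not match streamlines read (",
         trk$count, ")")
  }
  trk
}
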