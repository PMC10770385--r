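#' Tractogram: a bundle of streamlines in world coordinates
#'
#' A streamline is an ordered polyline of 3-D points (rows of an n x 3
#' matrix) in RAS world millimetres. The tractogram keeps the reference grid
#' geometry (affine + shape) it was defined against, so voxel-space
#' operations (envelopes, parcellations) are unambiguous.
#'
#' @param streamlines list of numeric matrices, each n_i x 3 with n_i >= 2.
#' @param reference a [scalar_volume()] (or a list with `affine` and `data`)
#'   providing the grid geometry.
#' @return An object of class `tractogram`.
#' @export
tractogram <- function(streamlines, reference) {
  streamlines <- lapply(streamlines, function(s) {
    s <- rbind_points(s)
    if (nrow(s) < 2L) stop("every streamline needs at least 2 points")
    if (!all(is.finite(s))) stop("streamline coordinates must be finite")
    if (streamline_length(s) <= 0) stop("streamline has zero arc length")
    unname(s)
  })
  structure(list(streamlines = streamlines, reference = reference),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  np <- vapply(x$streamlines, nrow, integer(1))
  cat(sprintf("<tractogram> %d streamlines, %d-%d points each\n",
              length(x$streamlines), min(np), max(np)))
  invisible(x)
}

#' @export
length.tractogram <- function(x) length(x$streamlines)

streamline_length <- function(s) {
  sum(sqrt(rowSums(diff(s)^2)))
}

#' Read a tractogram (TRK or TCK)
#'
#' Streamline points are returned in RAS world millimetres regardless of the
#' on-disk convention: TCK stores world mm directly, TRK stores
#' corner-origin voxel-mm which is normalized through the header's
#' voxel-to-RAS transform.
#'
#' @param path path to a `.trk` or `.tck` file.
#' @param reference a [scalar_volume()] giving the grid geometry the
#'   tractogram is analyzed against.
#' @return A [tractogram()].
#' @export
read_tractogram <- function(path, reference) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  sls <- switch(ext,
    trk = read_trk_streamlines(path),
    tck = read_tck_streamlines(path),
    stop("unknown tractogram format: .", ext, " (expected .trk or .tck)"))
  tractogram(sls, reference)
}

#' Write a tractogram (TRK or TCK)
#'
#' @param t a [tractogram()].
#' @param path output path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_tractogram <- function(t, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    trk = write_trk_streamlines(t$streamlines, t$reference, path),
    tck = write_tck_streamlines(t$streamlines, path),
    stop("unknown tractogram format: .", ext))
  invisible(path)
}

# ---- TCK (MRtrix): ASCII header, Float32LE triplets, NaN-delimited ----

read_tck_streamlines <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!identical(magic, "mrtrix tracks"))
    stop("not a TCK file (missing 'mrtrix tracks' magic): ", path)
  datatype <- "Float32LE"; offset <- NA_real_
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("truncated TCK header")
    if (identical(line, "END")) break
    kv <- regmatches(line, regexec("^([^:]+):\\s*(.*)$", line))[[1]]
    if (length(kv) == 3L) {
      key <- trimws(kv[2]); val <- trimws(kv[3])
      if (key == "datatype") datatype <- val
      if (key == "file") offset <- as.numeric(sub("^\\.\\s+", "", val))
    }
  }
  if (is.na(offset)) stop("TCK header missing 'file' offset")
  endian <- if (grepl("BE$", datatype)) "big" else "little"
  if (!grepl("^Float32", datatype)) stop("unsupported TCK datatype: ", datatype)
  seek(con, where = offset, origin = "start")
  raw <- readBin(con, "numeric", n = file.size(path), size = 4L,
                 endian = endian)
  m <- matrix(raw, ncol = 3L, byrow = TRUE)
  fin <- is.finite(m[, 1])
  breaks <- which(!fin)
  sls <- list(); start <- 1L
  for (b in breaks) {
    if (is.infinite(m[b, 1])) break
    if (b == start)
      stop("TCK contains a degenerate streamline record (empty)")
    sls[[length(sls) + 1L]] <- m[start:(b - 1L), , drop = FALSE]
    start <- b + 1L
  }
  if (any(vapply(sls, nrow, integer(1)) < 2L))
    stop("TCK contains a degenerate streamline record (<2 points)")
  sls
}

write_tck_streamlines <- function(streamlines, path) {
  hdr <- c("mrtrix tracks",
           "datatype: Float32LE",
           sprintf("count: %d", length(streamlines)))
  # reserve room for the 'file: . <offset>' line, then patch the offset
  probe <- paste(c(hdr, "file: . 000000", "END"), collapse = "\n")
  offset <- nchar(probe, type = "bytes") + 1L  # trailing newline
  hdr <- c(hdr, sprintf("file: . %06d", offset), "END")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  for (s in streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3L), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3L), con, size = 4L, endian = "little")
}

# ---- TRK (TrackVis): 1000-byte header, corner-origin voxel-mm points ----
# world = vox_to_ras %*% (p / voxel_size - 0.5): TRK's (0,0,0) is the corner
# of the first voxel, while the NIfTI affine maps voxel *centers*.

read_trk_streamlines <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 1000L)
  if (length(hdr) < 1000L) stop("truncated TRK header")
  magic <- rawToChar(hdr[1:5])
  if (!identical(magic, "TRACK")) stop("not a TRK file: ", path)
  rd <- function(off, what, n, size) {
    readBin(hdr[(off + 1L):1000L], what, n = n, size = size,
            endian = "little")
  }
  hdr_size <- rd(996L, "integer", 1L, 4L)
  if (hdr_size != 1000L) stop("unsupported TRK endianness or header size")
  voxel_size <- rd(12L, "numeric", 3L, 4L)
  n_scalars <- rd(36L, "integer", 1L, 2L)
  n_properties <- rd(238L, "integer", 1L, 2L)
  vox_to_ras <- matrix(rd(440L, "numeric", 16L, 4L), 4L, 4L, byrow = TRUE)
  n_count <- rd(988L, "integer", 1L, 4L)
  if (vox_to_ras[4L, 4L] == 0)
    stop("TRK header has no valid voxel-to-RAS transform")
  sls <- vector("list", max(n_count, 0L))
  i <- 0L
  repeat {
    np <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    if (length(np) == 0L) break
    if (np < 2L) stop("TRK contains a degenerate streamline record (<2 points)")
    vals <- readBin(con, "numeric", n = np * (3L + n_scalars), size = 4L,
                    endian = "little")
    if (n_properties > 0L)
      readBin(con, "numeric", n = n_properties, size = 4L, endian = "little")
    pts <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3,
                                                             drop = FALSE]
    vox <- sweep(pts, 2L, voxel_size, "/") - 0.5
    i <- i + 1L
    sls[[i]] <- voxel_to_world(vox, vox_to_ras)
  }
  sls[seq_len(i)]
}

write_trk_streamlines <- function(streamlines, reference, path) {
  affine <- reference$affine
  voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  dims <- dim(reference$data)
  inv <- solve(affine)
  hdr <- raw(1000L)
  put <- function(hdr, off, x, size) {
    b <- writeBin(x, raw(), size = size, endian = "little")
    hdr[(off + 1L):(off + length(b))] <- b
    hdr
  }
  hdr <- put(hdr, 0L, c(charToRaw("TRACK"), as.raw(0L)), 1L)
  hdr <- put(hdr, 6L, as.integer(dims), 2L)
  hdr <- put(hdr, 12L, as.numeric(voxel_size), 4L)
  hdr <- put(hdr, 36L, 0L, 2L)                       # n_scalars
  hdr <- put(hdr, 238L, 0L, 2L)                      # n_properties
  hdr <- put(hdr, 440L, as.numeric(t(affine)), 4L)   # vox_to_ras, row-major
  hdr <- put(hdr, 948L, c(charToRaw("RAS"), as.raw(0L)), 1L) # voxel_order
  hdr <- put(hdr, 988L, length(streamlines), 4L)     # n_count
  hdr <- put(hdr, 992L, 2L, 4L)                      # version
  hdr <- put(hdr, 996L, 1000L, 4L)                   # hdr_size
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  for (s in streamlines) {
    v <- cbind(rbind_points(s), 1) %*% t(inv)
    p <- sweep(v[, 1:3, drop = FALSE] + 0.5, 2L, voxel_size, "*")
    writeBin(nrow(p), con, size = 4L, endian = "little")
    writeBin(as.numeric(t(p)), con, size = 4L, endian = "little")
  }
}
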