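## TCK (MRtrix) and TRK (TrackVis) streamline I/O. TCK stores points in
## world/scanner mm directly; TRK stores voxel-mm coordinates with a
## corner-of-voxel origin, converted to world mm on read through the
## header's vox_to_ras matrix, so both readers return the same geometry.

#' Write streamlines to a TCK file
#'
#' @param bundle a [Bundle-class] (coordinates in world mm).
#' @param path output path.
#' @export
writeTck <- function(bundle, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0("mrtrix tracks\n",
                "datatype: Float32LE\n",
                "count: ", length(bundle@streamlines), "\n")
  # the offset line's own width feeds into the offset; iterate to fixpoint
  offset <- nchar(hdr)
  repeat {
    line <- paste0("file: . ", offset, "\nEND\n")
    if (nchar(hdr) + nchar(line) == offset) break
    offset <- nchar(hdr) + nchar(line)
  }
  writeChar(paste0(hdr, line), con, eos = NULL)
  for (s in bundle@streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read streamlines from a TCK file
#'
#' @param path TCK file path.
#' @param name,side stored on the returned [Bundle-class]; side defaults
#'   to a suffix-based guess from the name.
#' @export
readTck <- function(path, name = sub("\\.tck$", "", basename(path)),
                    side = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  if (!identical(first, "mrtrix tracks"))
    stop("malformed TCK header in ", path, ": missing magic line")
  fields <- list()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("truncated TCK header in ", path)
    if (ln == "END") break
    kv <- strsplit(ln, ": ", fixed = TRUE)[[1]]
    fields[[kv[1]]] <- paste(kv[-1], collapse = ": ")
  }
  if (is.null(fields$datatype) || fields$datatype != "Float32LE")
    stop("unsupported TCK datatype: ", fields$datatype)
  off <- as.integer(strsplit(fields$file, " ")[[1]][2])
  seek(con, off)
  raw <- readBin(con, "numeric", n = file.size(path), size = 4L,
                 endian = "little")
  m <- matrix(raw, ncol = 3L, byrow = TRUE)
  isEnd <- is.infinite(m[, 1])
  if (!any(isEnd))
    stop("truncated TCK file ", path, ": no end-of-file triplet (offset ",
         off + 12 * nrow(m), ")")
  m <- m[seq_len(which(isEnd)[1] - 1L), , drop = FALSE]
  breaks <- which(is.nan(m[, 1]))
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks - 1L, nrow(m))
  keep <- starts <= ends
  sl <- Map(function(a, b) m[a:b, , drop = FALSE],
            starts[keep], ends[keep])
  sl <- Filter(function(s) nrow(s) >= 2L, sl)
  if (is.null(side)) side <- bundleSide(name)
  new("Bundle", name = name, side = side, streamlines = unname(sl))
}

#' Write streamlines to a TRK (TrackVis) file
#'
#' Coordinates are converted from world mm to the TRK voxel-mm
#' convention using the grid affine, which is stored in the header's
#' vox_to_ras field.
#'
#' @param bundle a [Bundle-class].
#' @param grid the [VoxelGrid-class] defining the voxel frame.
#' @param path output path.
#' @export
writeTrk <- function(bundle, grid, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  vs <- voxelSize(grid)
  wch <- function(x, n) {
    r <- charToRaw(x)
    writeBin(c(r, raw(n - length(r))), con)
  }
  wch("TRACK", 6L)
  writeBin(as.integer(gridDim(grid)), con, size = 2L, endian = "little")
  writeBin(as.numeric(vs), con, size = 4L, endian = "little")
  writeBin(numeric(3), con, size = 4L, endian = "little")  # origin
  writeBin(0L, con, size = 2L, endian = "little")          # n_scalars
  writeBin(raw(200), con)                                  # scalar names
  writeBin(0L, con, size = 2L, endian = "little")          # n_properties
  writeBin(raw(200), con)                                  # property names
  writeBin(as.numeric(t(gridAffine(grid))), con, size = 4L,
           endian = "little")                              # vox_to_ras
  writeBin(raw(444), con)                                  # reserved
  wch("LPS", 4L)                                           # voxel_order
  writeBin(raw(4), con)                                    # pad2
  writeBin(numeric(6), con, size = 4L, endian = "little")  # img orient
  writeBin(raw(2), con)                                    # pad1
  writeBin(raw(6), con)                                    # invert/swap
  writeBin(length(bundle@streamlines), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 4L, endian = "little")          # version
  writeBin(1000L, con, size = 4L, endian = "little")       # hdr_size
  for (s in bundle@streamlines) {
    v <- worldToVoxel(grid, s)                 # continuous voxel coords
    p <- sweep(v + 0.5, 2, vs, "*")            # TRK voxel-mm (corner)
    writeBin(nrow(p), con, size = 4L, endian = "little")
    writeBin(as.numeric(t(p)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read streamlines from a TRK file
#'
#' @inheritParams readTck
#' @return A [Bundle-class] with coordinates in world mm.
#' @export
readTrk <- function(path, name = sub("\\.trk$", "", basename(path)),
                    side = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 5L))
  if (!identical(magic, "TRACK")) stop("malformed TRK header in ", path)
  readBin(con, "raw", 1L)
  dims <- readBin(con, "integer", 3L, size = 2L, endian = "little")
  vs <- readBin(con, "numeric", 3L, size = 4L, endian = "little")
  readBin(con, "numeric", 3L, size = 4L, endian = "little")
  nScalars <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  readBin(con, "raw", 200L)
  nProps <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  readBin(con, "raw", 200L)
  A <- matrix(readBin(con, "numeric", 16L, size = 4L, endian = "little"),
              4, 4, byrow = TRUE)
  readBin(con, "raw", 444L + 4L + 4L)
  readBin(con, "numeric", 6L, size = 4L, endian = "little")
  readBin(con, "raw", 2L + 6L)
  nCount <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  version <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hdrSize <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (hdrSize != 1000L)
    stop("unsupported TRK header size ", hdrSize, " in ", path)
  if (all(A == 0)) stop("TRK file ", path, " lacks a vox_to_ras matrix")
  sl <- list()
  repeat {
    np <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(np) == 0L) break
    vals <- readBin(con, "numeric", np * (3L + nScalars) + nProps,
                    size = 4L, endian = "little")
    if (length(vals) < np * (3L + nScalars) + nProps)
      stop("truncated TRK file ", path, " at streamline ",
           length(sl) + 1L)
    pm <- matrix(vals[seq_len(np * (3L + nScalars))],
                 ncol = 3L + nScalars, byrow = TRUE)[, 1:3, drop = FALSE]
    v <- sweep(pm, 2, vs, "/") - 0.5       # back to 0-based voxel coords
    w <- t(A %*% rbind(t(v), 1))[, 1:3, drop = FALSE]
    sl[[length(sl) + 1L]] <- w
  }
  if (nCount > 0L && length(sl) != nCount)
    warning("TRK header declared ", nCount, " tracks; read ", length(sl))
  if (is.null(side)) side <- bundleSide(name)
  new("Bundle", name = name, side = side, streamlines = sl)
}

#' Read a streamline file (TCK or TRK) into world mm
#'
#' @inheritParams readTck
#' @export
readStreamlines <- function(path, name = sub("\\.(tck|trk)$", "",
                                             basename(path)),
                            side = NULL) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tck = readTck(path, name = name, side = side),
         trk = readTrk(path, name = name, side = side),
         stop("unsupported streamline format: .", ext))
}
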