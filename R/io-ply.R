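## Point cloud file I/O: binary little-endian PLY with float32 x, y, z.

#' Read and write point clouds as binary PLY
#'
#' Binary little-endian PLY 1.0 with a single `vertex` element carrying
#' `float x`, `float y`, `float z`. The round trip is exact at float32
#' precision. Files without a PLY magic or with an unsupported layout raise a
#' format error.
#'
#' @param cloud a [PointCloud-class].
#' @param path file path.
#' @param frame frame label to attach on read (the format does not carry one).
#' @return `readPLY` returns a [PointCloud-class]; `writePLY` (invisibly)
#'   the path.
#' @export
writePLY <- function(cloud, path) {
  stopifnot(is(cloud, "PointCloud"))
  n <- nrow(cloud@points)
  hdr <- paste0("ply\nformat binary_little_endian 1.0\n",
                "comment bcs3d point cloud (mm)\n",
                sprintf("element vertex %d\n", n),
                "property float x\nproperty float y\nproperty float z\n",
                "end_header\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  if (n > 0)
    writeBin(as.vector(t(cloud@points)), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname writePLY
#' @export
readPLY <- function(path, frame = "camera") {
  if (!file.exists(path))
    bcsStop("formatError", sprintf("no such file: %s", path))
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 4 || rawToChar(raw[1:3]) != "ply")
    bcsStop("formatError", sprintf("not a PLY file (missing magic): %s", path))
  # locate end_header in the raw bytes (the binary body may contain NULs)
  tok <- charToRaw("end_header\n")
  endTok <- grepRaw("end_header\n", raw, fixed = TRUE)
  if (!length(endTok))
    bcsStop("formatError", sprintf("PLY header not terminated: %s", path))
  endTok <- endTok[1]
  hdr <- strsplit(rawToChar(raw[seq_len(endTok - 1)]), "\n", fixed = TRUE)[[1]]
  if (!any(grepl("^format binary_little_endian 1.0", hdr)))
    bcsStop("formatError",
            sprintf("unsupported PLY format (need binary_little_endian 1.0): %s", path))
  vline <- grep("^element vertex ", hdr, value = TRUE)
  if (length(vline) != 1)
    bcsStop("formatError", sprintf("PLY must declare one vertex element: %s", path))
  n <- as.integer(sub("^element vertex ", "", vline))
  props <- sub("^property float ", "", grep("^property float ", hdr, value = TRUE))
  if (!identical(props, c("x", "y", "z")))
    bcsStop("formatError",
            sprintf("unsupported PLY vertex layout (need float x, y, z): %s", path))
  off <- endTok + length(tok) - 1
  body <- if (off < length(raw)) raw[(off + 1):length(raw)] else raw(0)
  if (n > 0 && length(body) < 12 * n)
    bcsStop("formatError", sprintf("PLY vertex data truncated: %s", path))
  pts <- if (n > 0) {
    matrix(readBin(body, "double", n = 3L * n, size = 4, endian = "little"),
           ncol = 3, byrow = TRUE)
  } else matrix(numeric(0), 0, 3)
  PointCloud(pts, frame = frame)
}
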