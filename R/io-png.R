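## Depth map file I/O: 16-bit single-channel PNG (value = mm, 0 = invalid)
## plus a JSON sidecar `<name>.json` carrying intrinsics and metadata.

.pngChunk <- function(con, type, data) {
  writeBin(length(data), con, size = 4, endian = "big")
  payload <- c(charToRaw(type), data)
  writeBin(payload, con)
  crc <- .crc32Cpp(payload)
  writeBin(as.integer(crc - ifelse(crc > 2^31 - 1, 2^32, 0)), con,
           size = 4, endian = "big")
}

# minimal 16-bit grayscale PNG writer (zlib stream via memCompress)
.writePNG16 <- function(m, path) {
  h <- nrow(m); w <- ncol(m)
  vals <- as.integer(round(t(m)))  # row-major scanlines
  vals <- pmin(65535L, pmax(0L, vals))
  hi <- as.raw(vals %/% 256L)
  lo <- as.raw(vals %% 256L)
  px <- as.vector(rbind(hi, lo))               # big-endian 16-bit samples
  dim(px) <- NULL
  scan <- matrix(px, nrow = 2L * w, ncol = h)  # one column per scanline
  raw_rows <- as.raw(rbind(matrix(as.raw(0), 1, h), scan))  # filter byte 0
  idat <- memCompress(as.vector(raw_rows), type = "gzip")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)), con)
  ihdr <- c(writeBin(as.integer(w), raw(), size = 4, endian = "big"),
            writeBin(as.integer(h), raw(), size = 4, endian = "big"),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))  # depth 16, grayscale, no interlace
  .pngChunk(con, "IHDR", ihdr)
  .pngChunk(con, "IDAT", idat)
  .pngChunk(con, "IEND", raw(0))
  invisible(path)
}

.sidecarPath <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Read and write depth maps as 16-bit PNG with a JSON sidecar
#'
#' The PNG stores depth in mm as 16-bit grayscale with sentinel 0 for invalid
#' pixels; the sidecar `<name>.json` stores `fx, fy, cx, cy, width, height,
#' baseline_mm, frame_id, timestamp`. The round trip is bit-exact for
#' integer-mm depth maps. Non-16-bit or non-grayscale input and missing or
#' unparsable sidecars raise a format error naming the path.
#'
#' @param depth a [DepthMap-class].
#' @param path PNG file path.
#' @return `readDepthPNG` returns a [DepthMap-class]; `writeDepthPNG`
#'   (invisibly) the path.
#' @export
writeDepthPNG <- function(depth, path) {
  stopifnot(is(depth, "DepthMap"))
  vals <- round(depth@values)
  vals[!depth@valid] <- 0
  vals[depth@valid & vals < 1] <- 1  # keep sentinel reserved for invalid
  .writePNG16(vals, path)
  cam <- depth@intrinsics
  side <- list(fx = cam@fx, fy = cam@fy, cx = cam@cx, cy = cam@cy,
               width = cam@width, height = cam@height,
               baseline_mm = cam@baseline,
               frame_id = depth@frameId, timestamp = depth@timestamp)
  jsonlite::write_json(side, .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# parse IHDR to enforce the declared format before handing off to png::readPNG
.pngHeaderInfo <- function(path) {
  hdr <- readBin(path, "raw", n = 26)
  sig <- as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A))
  if (length(hdr) < 26 || !identical(hdr[1:8], sig))
    bcsStop("formatError", sprintf("not a PNG file: %s", path))
  list(bitDepth = as.integer(hdr[25]), colorType = as.integer(hdr[26]))
}

#' @rdname writeDepthPNG
#' @export
readDepthPNG <- function(path) {
  if (!file.exists(path))
    bcsStop("formatError", sprintf("no such file: %s", path))
  info <- .pngHeaderInfo(path)
  if (info$bitDepth != 16L)
    bcsStop("formatError",
            sprintf("expected 16-bit depth PNG, got %d-bit: %s", info$bitDepth, path))
  if (info$colorType != 0L)
    bcsStop("formatError", sprintf("expected grayscale PNG: %s", path))
  sp <- .sidecarPath(path)
  if (!file.exists(sp))
    bcsStop("formatError", sprintf("missing intrinsics sidecar: %s", sp))
  side <- tryCatch(jsonlite::read_json(sp, simplifyVector = TRUE),
                   error = function(e)
                     bcsStop("formatError", sprintf("corrupt sidecar JSON: %s", sp)))
  need <- c("fx", "fy", "cx", "cy", "width", "height", "baseline_mm")
  if (!all(need %in% names(side)))
    bcsStop("formatError", sprintf("sidecar missing required fields: %s", sp))
  vals <- round(png::readPNG(path) * 65535)
  cam <- CameraIntrinsics(side$fx, side$fy, side$cx, side$cy,
                          side$width, side$height, side$baseline_mm)
  DepthMap(values = vals, valid = vals > 0, intrinsics = cam,
           frameId = side$frame_id %||% "frame",
           timestamp = side$timestamp %||% "1970-01-01T00:00:00Z")
}
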