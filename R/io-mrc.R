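#' @title MRC image IO
#' @description
#' Minimal reader/writer for 2-D MRC images (mode 2, 32-bit float), the
#' standard electron-microscopy image format. Only single 2-D images are
#' handled; volumes and stacks are rejected. Pixel size is carried in the
#' header cell dimensions (`cella / mx`). Writes are atomic
#' (write-to-temp, rename).
#' @name io-mrc
NULL

#' Read a 2-D MRC micrograph
#'
#' @param path path to an MRC file
#' @return a [Micrograph-class]
#' @export
readMRC <- function(path) {
  if (!file.exists(path)) stop("MRC file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 10L, size = 4L, endian = "little")
  nx <- hdr_int[1L]; ny <- hdr_int[2L]; nz <- hdr_int[3L]; mode <- hdr_int[4L]
  if (mode != 2L) stop("unsupported MRC mode ", mode, " (expected mode 2, float32)")
  if (nz != 1L) stop("expected 2-D micrograph, got nz = ", nz)
  if (nx < 1L || ny < 1L) stop("invalid MRC dimensions")
  mxyz <- hdr_int[8:10]                 # words 8-10: mx, my, mz
  cella <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  seek(con, 92L)  # word 24: nsymbt, bytes of extended header
  nsymbt <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  seek(con, 1024L + nsymbt)
  vals <- readBin(con, "numeric", n = nx * ny, size = 4L, endian = "little")
  if (length(vals) != nx * ny) stop("truncated MRC data section")
  # data are written x-fastest; our matrices are rows = y, cols = x
  px <- t(matrix(vals, nx, ny))
  ps <- if (mxyz[1L] > 0L && cella[1L] > 0) cella[1L] / mxyz[1L] else NA_real_
  Micrograph(px, pixelSize = ps, id = sub("\\.mrc$", "", basename(path)))
}

#' Write a 2-D MRC micrograph (mode 2)
#'
#' @param micrograph a [Micrograph-class] (or plain numeric matrix)
#' @param path output path
#' @return invisibly, `path`
#' @export
writeMRC <- function(micrograph, path) {
  if (is.matrix(micrograph)) micrograph <- Micrograph(micrograph)
  stopifnot(is(micrograph, "Micrograph"))
  px <- micrograph@pixels
  H <- nrow(px); W <- ncol(px)
  ps <- micrograph@pixelSize
  tmp <- paste0(path, ".tmp", Sys.getpid())
  con <- file(tmp, "wb")
  ok <- FALSE
  on.exit({
    close(con)
    if (ok) file.rename(tmp, path) else unlink(tmp)
  })
  writeBin(as.integer(c(W, H, 1L, 2L, 0L, 0L, 0L, W, H, 1L)), con,
           size = 4L, endian = "little")
  cell <- if (is.na(ps)) c(W, H, 1) else c(W * ps, H * ps, ps)
  writeBin(as.numeric(c(cell, 90, 90, 90)), con, size = 4L, endian = "little")
  writeBin(as.integer(c(1L, 2L, 3L)), con, size = 4L, endian = "little")
  writeBin(as.numeric(c(min(px), max(px), mean(px))), con, size = 4L, endian = "little")
  writeBin(as.integer(c(0L, 0L)), con, size = 4L, endian = "little")   # ispg, nsymbt
  writeBin(raw(100L), con)                                             # extra
  writeBin(as.numeric(c(0, 0, 0)), con, size = 4L, endian = "little")  # origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)                     # machst LE
  writeBin(as.numeric(stats::sd(px)), con, size = 4L, endian = "little")
  writeBin(as.integer(1L), con, size = 4L, endian = "little")          # nlabl
  lab <- sprintf("%-80s", "PromptPick")
  writeBin(charToRaw(paste0(lab, strrep(" ", 80 * 9))), con)
  writeBin(as.numeric(t(px)), con, size = 4L, endian = "little")       # x fastest
  ok <- TRUE
  invisible(path)
}
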