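#' @title STAR / CSV / PNG particle and preview IO
#' @description
#' RELION-style STAR coordinate files (plain `loop_` blocks with
#' `_rlnCoordinateX` / `_rlnCoordinateY`, confidences as
#' `_rlnAutopickFigureOfMerit`), a simple `x,y,confidence` CSV dialect, and
#' 8-bit PNG previews (min-max normalized, preview only). All writes are
#' atomic.
#' @name io-star
NULL

atomicWrite <- function(lines, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    stop("could not write ", path)
  }
  invisible(path)
}

#' Read particle coordinates from a STAR file
#'
#' Parses the first `loop_` block containing `_rlnCoordinateX` and
#' `_rlnCoordinateY`. A `_rlnAutopickFigureOfMerit` column, when present,
#' is read as the per-particle confidence; otherwise confidences default
#' to 1.
#'
#' @param path path to a STAR file
#' @param diameter nominal particle diameter to attach (pixels)
#' @param micrographId id to attach
#' @return a [ParticleSet-class]
#' @export
readSTAR <- function(path, diameter = NA_real_, micrographId = "") {
  if (!file.exists(path)) stop("STAR file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  labels <- character(0)
  rows <- list()
  in_loop <- FALSE
  for (ln in lines) {
    if (ln == "loop_") {
      in_loop <- TRUE; labels <- character(0); rows <- list()
      next
    }
    if (!in_loop) next
    if (startsWith(ln, "_")) {
      labels <- c(labels, sub("\\s+#\\d+$", "", ln))
    } else if (startsWith(ln, "data_")) {
      if (length(rows)) break
      in_loop <- FALSE
    } else {
      rows[[length(rows) + 1L]] <- strsplit(ln, "\\s+")[[1L]]
    }
  }
  need <- c("_rlnCoordinateX", "_rlnCoordinateY")
  missing <- setdiff(need, labels)
  if (length(missing)) {
    stop("STAR file ", path, " lacks required coordinate label(s): ",
         paste(missing, collapse = ", "))
  }
  ix <- match("_rlnCoordinateX", labels)
  iy <- match("_rlnCoordinateY", labels)
  ic <- match("_rlnAutopickFigureOfMerit", labels)
  if (!length(rows)) return(ParticleSet(diameter = diameter, micrographId = micrographId))
  bad <- vapply(rows, length, integer(1L)) < length(labels)
  if (any(bad)) stop("STAR data row has fewer fields than labels in ", path)
  xs <- as.numeric(vapply(rows, `[[`, character(1L), ix))
  ys <- as.numeric(vapply(rows, `[[`, character(1L), iy))
  cf <- if (is.na(ic)) rep(1, length(xs))
        else as.numeric(vapply(rows, `[[`, character(1L), ic))
  ParticleSet(cbind(xs, ys), confidences = cf, diameter = diameter,
              micrographId = micrographId)
}

#' Write particle coordinates as a STAR file
#'
#' @param particles a [ParticleSet-class]
#' @param path output path
#' @param writeConfidence include `_rlnAutopickFigureOfMerit`
#' @return invisibly, `path`
#' @export
writeSTAR <- function(particles, path, writeConfidence = TRUE) {
  stopifnot(is(particles, "ParticleSet"))
  header <- c("", "data_", "", "loop_",
              "_rlnCoordinateX #1", "_rlnCoordinateY #2")
  if (writeConfidence) header <- c(header, "_rlnAutopickFigureOfMerit #3")
  n <- nrow(particles@coords)
  body <- character(0)
  if (n > 0L) {
    fx <- format(particles@coords[, 1L], trim = TRUE, digits = 10, scientific = FALSE)
    fy <- format(particles@coords[, 2L], trim = TRUE, digits = 10, scientific = FALSE)
    body <- if (writeConfidence) {
      fc <- format(particles@confidences, trim = TRUE, digits = 6, scientific = FALSE)
      paste(fx, fy, fc)
    } else paste(fx, fy)
  }
  atomicWrite(c(header, body, ""), path)
}

#' Read particles from a `x,y,confidence` CSV
#'
#' @param path CSV with columns `x`, `y` and optional `confidence`
#' @param diameter,micrographId metadata to attach
#' @return a [ParticleSet-class]
#' @export
readCoordCSV <- function(path, diameter = NA_real_, micrographId = "") {
  df <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(df))) {
    stop("coordinate CSV must have columns 'x' and 'y': ", path)
  }
  cf <- if ("confidence" %in% names(df)) df$confidence else rep(1, nrow(df))
  ParticleSet(cbind(df$x, df$y), confidences = cf, diameter = diameter,
              micrographId = micrographId)
}

#' Write particles as `x,y,confidence` CSV
#' @param particles a [ParticleSet-class]
#' @param path output path
#' @return invisibly, `path`
#' @export
writeCoordCSV <- function(particles, path) {
  df <- data.frame(x = particles@coords[, 1L], y = particles@coords[, 2L],
                   confidence = particles@confidences)
  tmp <- paste0(path, ".tmp", Sys.getpid())
  utils::write.csv(df, tmp, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Write an 8-bit PNG preview of an image
#'
#' Min-max normalizes to `[0, 1]` for display; never used for computation.
#'
#' @param x [Micrograph-class] or numeric matrix
#' @param path output path
#' @return invisibly, `path`
#' @export
writePreviewPNG <- function(x, path) {
  if (is(x, "Micrograph")) x <- x@pixels
  rng <- range(x)
  z <- if (diff(rng) > 0) (x - rng[1L]) / diff(rng) else x * 0
  png::writePNG(z, path)
  invisible(path)
}
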