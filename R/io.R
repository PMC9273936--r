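#' Read a grayscale image as a rough surface
#'
#' Imports TIFF, PNG or PGM (P2/P5) images.  Multi-channel images are
#' averaged to one channel.  If a JSON metadata sidecar written by
#' [write_surface()] sits next to the file (`<path>.json`), the recorded
#' height scale and provenance (Hurst exponent, seed, saturation) are
#' restored; otherwise heights are used as stored.
#'
#' @param path image file; format chosen by extension
#'   (`.tif`/`.tiff`, `.png`, `.pgm`).
#' @return A [rough_surface()] with `periodic = FALSE`.
#' @export
read_surface <- function(path) {
  ext <- tolower(tools::file_ext(path))
  mat <- switch(ext,
    tif = , tiff = {
      img <- tiff::readTIFF(path)
      if (length(dim(img)) == 3L) img <- rowMeans(img, dims = 2L)
      img
    },
    png = {
      img <- png::readPNG(path)
      if (length(dim(img)) == 3L) img <- rowMeans(img, dims = 2L)
      img
    },
    pgm = read_pgm(path),
    stop("unsupported image extension: ", ext))
  # image row 1 is the top scanline; transpose so rows index x, columns y
  mat <- t(mat)
  meta_path <- paste0(path, ".json")
  hurst <- NULL; seed <- NULL; saturation <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$height_scale)) mat <- mat * meta$height_scale
    hurst <- meta$hurst
    seed <- meta$seed
    if (!is.null(meta$saturation) && length(meta$saturation)) {
      saturation <- as.list(meta$saturation)
    }
  }
  rough_surface(mat, hurst = hurst, seed = seed, saturation = saturation,
                periodic = FALSE)
}

#' Write a surface as 32-bit float TIFF plus JSON sidecar
#'
#' Heights are stored divided by `height_scale` (so the calibrated
#' [0, 255] range maps into the [0, 1] float-TIFF convention); the
#' sidecar `<path>.json` records the scale and the surface provenance so
#' [read_surface()] round-trips losslessly up to float precision.
#'
#' @param surface a [rough_surface()].
#' @param path output `.tif` path.
#' @param height_scale divisor applied before writing (default 255).
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path, height_scale = 255) {
  stopifnot(inherits(surface, "rough_surface"))
  tiff::writeTIFF(t(surface$heights) / height_scale, path,
                  bits.per.sample = 32L, reduce = FALSE)
  meta <- list(height_scale = height_scale, size = surface$size,
               hurst = surface$hurst, seed = surface$seed,
               saturation = surface$saturation)
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1L))],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Minimal PGM reader (ascii P2 and binary P5, 8- or 16-bit).
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop("unexpected end of PGM header")
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (!length(ch) || ch == "\n") break
        }
      } else if (!grepl("^[[:space:]]$", ch)) break
    }
    out <- ch
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (!length(ch) || grepl("^[[:space:]]$", ch)) break
      out <- paste0(out, ch)
    }
    out
  }
  magic <- tok()
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", magic)
  w <- as.integer(tok()); h <- as.integer(tok()); maxv <- as.integer(tok())
  npix <- w * h
  vals <- if (magic == "P2") {
    scan(con, what = integer(), n = npix, quiet = TRUE)
  } else if (maxv < 256L) {
    as.integer(readBin(con, "raw", n = npix))
  } else {
    readBin(con, "integer", n = npix, size = 2L, signed = FALSE,
            endian = "big")
  }
  if (length(vals) != npix) stop("truncated PGM data")
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}
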