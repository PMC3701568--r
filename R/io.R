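# Image and mask readers/writers: PNG (8-bit), TIFF (8/16-bit, values
# preserved un-rescaled, multi-page for volumes) and plain ASCII/binary PGM.
# Intensities are float matrices throughout the package; files on the
# integer scale of their bit depth.

img_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png")) return("png")
  if (ext %in% c("tif", "tiff")) return("tiff")
  if (ext %in% c("pgm")) return("pgm")
  stop(sprintf("unsupported image format: '%s'", path), call. = FALSE)
}

rgb_to_gray <- function(a) {
  if (length(dim(a)) == 3L) {
    warning("RGB input demoted to luminance", call. = FALSE)
    a <- 0.2989 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
  }
  a
}

#' Read a grayscale image as a float matrix
#'
#' PNG values are returned on the 0..255 scale; TIFF values are read
#' unscaled (16-bit data keeps its native 0..65535 range); PGM (P2/P5)
#' values are read as stored. RGB input is demoted to luminance
#' (0.2989 R + 0.587 G + 0.114 B) with a warning.
#'
#' @param path file path (.png, .tif/.tiff, .pgm).
#' @return numeric matrix.
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read image: '%s' does not exist", path),
         call. = FALSE)
  switch(img_format(path),
    png = rgb_to_gray(png::readPNG(path)) * 255,
    tiff = {
      a <- tiff::readTIFF(path, as.is = TRUE)
      rgb_to_gray(a) * 1.0
    },
    pgm = read_pgm(path))
}

#' Write a float matrix as a grayscale image
#'
#' PNG: values are clamped to [0, 255] and written 8-bit. TIFF: written
#' 16-bit, values clamped to [0, 65535]. PGM: ASCII P2 at the matrix's
#' integer values (max 65535).
#'
#' @param image numeric matrix.
#' @param path output path; the extension selects the format.
#' @return \code{path}, invisibly.
#' @export
write_image <- function(image, path) {
  switch(img_format(path),
    png = png::writePNG(pmin(pmax(image, 0), 255) / 255, path),
    tiff = tiff::writeTIFF(pmin(pmax(image, 0), 65535) / 65535, path,
                           bits.per.sample = 16L),
    pgm = write_pgm(image, path))
  invisible(path)
}

read_pgm <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  tok <- character(0)
  # header: magic, width, height, maxval (comments start with #)
  while (length(tok) < 4L) {
    line <- readLines(con, n = 1L)
    line <- sub("#.*", "", line)
    tok <- c(tok, strsplit(trimws(line), "\\s+")[[1]])
    tok <- tok[nzchar(tok)]
  }
  magic <- tok[1]
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  maxval <- as.integer(tok[4])
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = w * h, quiet = TRUE)
  } else if (magic == "P5") {
    sz <- if (maxval > 255) 2L else 1L
    vals <- readBin(con, "integer", n = w * h, size = sz, signed = FALSE,
                    endian = "big")
  } else stop("not a PGM (P2/P5) file", call. = FALSE)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) * 1.0
}

write_pgm <- function(image, path) {
  v <- round(pmin(pmax(image, 0), 65535))
  maxval <- max(255, max(v))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("P2", paste(ncol(image), nrow(image)),
               as.character(as.integer(maxval))), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read binary masks
#'
#' 2D masks are serialized as 0/255 8-bit PNG; 3D masks as multi-page TIFF
#' (one page per slice along the third dimension). Round trips are exact.
#'
#' @param mask logical (or strictly 0/1) 2D or 3D array.
#' @param path file path (.png for 2D, .tif/.tiff for 2D or 3D).
#' @return \code{write_mask}: \code{path} invisibly; \code{read_mask}: a
#'   logical array.
#' @export
write_mask <- function(mask, path) {
  mask <- as_binary(mask)  # errors on non-binary input
  nd <- length(dim(mask))
  fmt <- img_format(path)
  if (nd == 2L) {
    if (fmt == "png") png::writePNG(mask * 1, path)
    else if (fmt == "tiff") tiff::writeTIFF(mask * 1, path,
                                            bits.per.sample = 8L)
    else write_pgm(mask * 255, path)
  } else if (nd == 3L) {
    if (fmt != "tiff")
      stop("3D masks must be written as multi-page TIFF", call. = FALSE)
    pages <- lapply(seq_len(dim(mask)[3]), function(k) mask[, , k] * 1)
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  } else stop("mask must be 2D or 3D", call. = FALSE)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read mask: '%s' does not exist", path),
         call. = FALSE)
  fmt <- img_format(path)
  if (fmt == "tiff") {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (is.list(pages) && length(pages) > 1L) {
      out <- array(FALSE, c(dim(pages[[1]])[1:2], length(pages)))
      for (k in seq_along(pages)) out[, , k] <- rgb_to_gray(pages[[k]]) > 0.5
      return(out)
    }
    a <- if (is.list(pages)) pages[[1]] else pages
    return(rgb_to_gray(a) > 0.5)
  }
  read_image(path) > 127
}

#' Read an ordered stack of slices
#'
#' Either a directory of single-slice images (filename order) or a single
#' multi-page TIFF.
#'
#' @param path directory or multi-page TIFF path.
#' @return list of numeric matrices.
#' @export
read_stack <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, full.names = TRUE,
                             pattern = "\\.(png|tif|tiff|pgm)$",
                             ignore.case = TRUE))
    if (length(files) == 0L)
      stop(sprintf("no image files found in '%s'", path), call. = FALSE)
    return(lapply(files, read_image))
  }
  if (!file.exists(path))
    stop(sprintf("cannot read stack: '%s' does not exist", path),
         call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(a) rgb_to_gray(a) * 1.0)
}
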