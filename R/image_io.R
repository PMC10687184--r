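#' Validate and normalize a color image array
#'
#' Internal helper: checks that `x` is a numeric H x W x 3 array with values
#' in [0, 255].  A matrix (grayscale) is replicated to three channels.
#'
#' @param x numeric array or matrix.
#' @param arg name used in error messages.
#' @return numeric array of dimension c(H, W, 3).
#' @keywords internal
as_image <- function(x, arg = "image") {
  if (is.matrix(x)) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop(sprintf("`%s` must be an H x W x 3 numeric array", arg))
  if (!is.numeric(x)) stop(sprintf("`%s` must be numeric", arg))
  if (anyNA(x)) stop(sprintf("`%s` contains missing values", arg))
  storage.mode(x) <- "double"
  x
}

#' Clip intensities to the 8-bit dynamic range
#'
#' @param x numeric array.
#' @return `x` with every value forced into [0, 255].
#' @export
clip255 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

# round-half-up to integers (R's round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

#' Read an RGB raster image
#'
#' Reads a PNG, TIFF or binary PPM (P6) file into the package's canonical
#' representation: a numeric `H x W x 3` array with intensities in
#' \code{[0, 255]}.  Grayscale inputs are replicated to three channels;
#' an alpha channel is dropped with a warning; 16-bit inputs are rescaled
#' to the 8-bit range.
#'
#' @param path path to a `.png`, `.tif`/`.tiff`, or `.ppm` file.
#' @return numeric array of dimension `c(H, W, 3)`, values in [0, 255].
#' @seealso [write_image()]
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    ppm  = return(read_ppm(path)),
    stop("unsupported image format: .", ext, " (use png, tiff or ppm)")
  )
  if (is.matrix(img)) {
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  } else if (length(dim(img)) == 3L && dim(img)[3] == 2L) {
    # gray + alpha
    warning("alpha channel dropped when reading ", path)
    g <- img[, , 1L]
    img <- array(rep(g, 3L), dim = c(dim(g), 3L))
  } else if (length(dim(img)) == 3L && dim(img)[3] == 4L) {
    warning("alpha channel dropped when reading ", path)
    img <- img[, , 1:3, drop = FALSE]
  } else if (length(dim(img)) != 3L || dim(img)[3] != 3L) {
    stop("unsupported channel layout in ", path)
  }
  out <- img * 255
  # snap to integers where the 8-bit quantization is recoverable, so that
  # write_image() -> read_image() round-trips bit-exactly
  r <- round_half_up(out)
  snap <- abs(out - r) < 1e-6
  out[snap] <- r[snap]
  out
}

#' Write an RGB image to disk
#'
#' Values are rounded half-up to the nearest integer, clipped to [0, 255]
#' and written as 8-bit RGB.  The format is chosen from the file extension
#' (PNG, TIFF or binary PPM).
#'
#' @param image numeric `H x W x 3` array (any real values; quantized here).
#' @param path output path ending in `.png`, `.tif`/`.tiff` or `.ppm`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  image <- as_image(image)
  q <- clip255(round_half_up(image))
  ext <- tolower(tools::file_ext(path))
  if (!dir.exists(dirname(path)))
    stop("cannot write image: directory does not exist: ", dirname(path))
  switch(ext,
    png  = png::writePNG(q / 255, path),
    tif  = ,
    tiff = tiff::writeTIFF(q / 255, path, bits.per.sample = 8L),
    ppm  = write_ppm(q, path),
    stop("unsupported image format: .", ext, " (use png, tiff or ppm)")
  )
  invisible(path)
}

# Binary PPM (P6), 8-bit, maxval 255.  No installed R package reads PPM,
# so the codec is implemented here; the format is three ASCII header tokens
# followed by raw interleaved RGB bytes.
read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- function() {
    # skip whitespace and '#' comments, return next token
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop("truncated PPM header in ", path)
      if (ch == "#") {
        repeat {
          c2 <- readChar(con, 1L, useBytes = TRUE)
          if (length(c2) == 0L || c2 == "\n") break
        }
      } else if (!grepl("[[:space:]]", ch)) {
        out <- ch
        repeat {
          c2 <- readChar(con, 1L, useBytes = TRUE)
          if (length(c2) == 0L || grepl("[[:space:]]", c2)) break
          out <- paste0(out, c2)
        }
        return(out)
      }
    }
  }
  magic <- tok()
  if (magic != "P6") stop("not a binary PPM (P6) file: ", path)
  w <- as.integer(tok()); h <- as.integer(tok()); maxval <- as.integer(tok())
  if (is.na(w) || is.na(h) || is.na(maxval) || maxval <= 0L || maxval > 255L)
    stop("unsupported PPM header in ", path)
  raw <- readBin(con, "integer", n = 3L * w * h, size = 1L, signed = FALSE)
  if (length(raw) < 3L * w * h) stop("truncated PPM pixel data in ", path)
  vals <- as.numeric(raw) * (255 / maxval)
  # stored pixel-interleaved row by row: (r,g,b)(r,g,b)...
  a <- array(vals, dim = c(3L, w, h))
  aperm(a, c(3L, 2L, 1L))
}

write_ppm <- function(q, path) {
  h <- dim(q)[1]; w <- dim(q)[2]
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P6\n%d %d\n255\n", w, h), con, eos = NULL)
  bytes <- as.integer(aperm(q, c(3L, 2L, 1L)))
  writeBin(bytes, con, size = 1L)
  invisible(path)
}

#' Pad an image by mirror reflection
#'
#' Reflect-without-repeat padding (the border pixel itself is not
#' duplicated): a row `a b c` padded by 2 becomes `c b a b c b a`.
#' All patch and block extraction near image borders operates on a
#' reflect-padded copy so that windows are always complete.
#'
#' @param image numeric `H x W x 3` array (or H x W matrix).
#' @param margin number of pixels to add on every side; must satisfy
#'   `margin < min(H, W)` for reflect-without-repeat to be defined.
#' @param mode `"reflect"` (default), `"replicate"` or `"zero"`; the
#'   alternatives exist for border-sensitivity checks.
#' @return padded array of dimension `c(H + 2 margin, W + 2 margin, 3)`.
#' @export
pad_image <- function(image, margin, mode = c("reflect", "replicate", "zero")) {
  mode <- match.arg(mode)
  is_mat <- is.matrix(image)
  image <- if (is_mat) image else as_image(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (margin < 0) stop("`margin` must be >= 0")
  margin <- as.integer(margin)
  if (margin == 0L) return(image)
  idx <- function(nn) {
    if (mode == "zero") return(NULL)
    i <- seq.int(-margin + 1L, nn + margin)
    if (mode == "replicate") return(pmin(pmax(i, 1L), nn))
    if (margin >= nn) stop("`margin` must be smaller than the image side")
    # reflect without repeating the edge sample: period 2(n-1)
    j <- (i - 1L) %% (2L * (nn - 1L))
    j <- ifelse(j >= nn, 2L * (nn - 1L) - j, j)
    j + 1L
  }
  if (mode == "zero") {
    dims <- dim(image) + if (is_mat) c(2L * margin, 2L * margin) else
      c(2L * margin, 2L * margin, 0L)
    out <- array(0, dim = dims)
    if (is_mat) out[margin + seq_len(h), margin + seq_len(w)] <- image
    else out[margin + seq_len(h), margin + seq_len(w), ] <- image
    return(out)
  }
  ri <- idx(h); ci <- idx(w)
  if (is_mat) image[ri, ci, drop = FALSE] else image[ri, ci, , drop = FALSE]
}
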