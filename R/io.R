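# Image input: PNG / TIFF / BMP / JPEG silhouettes -> grayscale matrix.

#' Read a grayscale image
#'
#' Reads PNG, TIFF, JPEG or simple uncompressed BMP files and returns an
#' intensity matrix in [0, 255] (row 1 = image top). Multi-channel images
#' are averaged to one channel; 16-bit inputs are rescaled to the 8-bit
#' range.
#'
#' @param path Image file path.
#' @return Numeric matrix of intensities in [0, 255].
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    bmp = read_bmp_gray(path),
    stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(a)) == 3L) a <- apply(a[, , seq_len(min(3L, dim(a)[3L])),
                                         drop = FALSE], c(1L, 2L), mean)
  if (max(a) <= 1) a <- a * 255
  round(a)
}

# minimal reader for uncompressed 8-bit / 24-bit BI_RGB BMP files
read_bmp_gray <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 2L)
  if (!identical(rawToChar(hdr), "BM")) stop("not a BMP file", call. = FALSE)
  readBin(con, "integer", 2L, size = 4L)              # file size + reserved
  offset <- readBin(con, "integer", 1L, size = 4L)
  readBin(con, "integer", 1L, size = 4L)              # DIB header size
  w <- readBin(con, "integer", 1L, size = 4L)
  h <- readBin(con, "integer", 1L, size = 4L)
  readBin(con, "integer", 1L, size = 2L)              # planes
  bpp <- readBin(con, "integer", 1L, size = 2L)
  comp <- readBin(con, "integer", 1L, size = 4L)
  if (comp != 0L || !(bpp %in% c(8L, 24L)))
    stop("only uncompressed 8-bit or 24-bit BMP supported", call. = FALSE)
  seek(con, offset)
  bypp <- bpp %/% 8L
  stride <- ((w * bypp + 3L) %/% 4L) * 4L
  raw <- readBin(con, "raw", stride * abs(h))
  m <- matrix(0, abs(h), w)
  for (i in seq_len(abs(h))) {
    rowbytes <- as.integer(raw[((i - 1L) * stride + 1L):((i - 1L) * stride + w * bypp)])
    px <- if (bypp == 1L) rowbytes else
      colMeans(matrix(rowbytes, nrow = 3L))
    # BMP rows are stored bottom-up when height is positive
    r <- if (h > 0L) abs(h) - i + 1L else i
    m[r, ] <- px
  }
  m
}
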