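# Image import/export. Canonical in-memory form: integer matrix (grey) or
# h x w x 3 array (RGB), values 0..255, dim = c(height, width[, channel]).

# matrix (h x w, 0..255) <-> EBImage Image (x, y, [0,1])
as_ebi <- function(m) EBImage::Image(t(m) / 255)
from_ebi <- function(e) {
  d <- EBImage::imageData(e)
  m <- round(pmin(pmax(t(d), 0), 1) * 255)
  storage.mode(m) <- "integer"
  m
}

#' Load a micrograph from disk
#'
#' Reads a BMP, JPG or PNG image into the package's canonical pixel array:
#' an integer matrix (greyscale) or height x width x 3 array (RGB) with
#' values in 0..255. JPG/PNG decoding is delegated to EBImage; BMP files
#' (uncompressed 8-bit palette or 24-bit) are read natively. 16-bit inputs
#' are rejected.
#'
#' @param path path to a BMP, JPG/JPEG or PNG file.
#' @return integer pixel array, `dim = c(height, width)` or
#'   `c(height, width, 3)`.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(width = 640, height = 480, seed = 3))
#' f <- tempfile(fileext = ".jpg")
#' write_image(ph$image, f)
#' img <- load_image(f)
#' dim(img)
load_image <- function(path) {
  if (!file.exists(path)) bq_stop("bq_input_error", paste("no such file:", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "bmp") return(read_bmp(path))
  if (!ext %in% c("jpg", "jpeg", "png"))
    bq_stop("bq_format_error", paste("unsupported image format:", ext))
  if (ext == "png" && png_bit_depth(path) > 8)
    bq_stop("bq_format_error", "16-bit images are not supported")
  e <- tryCatch(EBImage::readImage(path),
                error = function(err) bq_stop("bq_format_error",
                  paste("cannot decode", path, ":", conditionMessage(err))))
  d <- EBImage::imageData(e)
  if (length(dim(d)) == 2) {
    from_ebi(e)
  } else {
    nch <- dim(d)[3]
    if (!nch %in% c(3, 4))
      bq_stop("bq_format_error", paste("unsupported channel count:", nch))
    out <- array(0L, c(dim(d)[2], dim(d)[1], 3))
    for (k in 1:3) out[, , k] <- as.integer(round(pmin(pmax(t(d[, , k]), 0), 1) * 255))
    out
  }
}

png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 25)
  if (length(hdr) < 25) return(8L)
  as.integer(hdr[25])
}

#' Write an image to disk
#'
#' Writes a canonical pixel array (greyscale matrix or RGB array, 0..255) as
#' JPG (quality 95), PNG, or uncompressed BMP.
#'
#' @param img pixel array as returned by [load_image()].
#' @param path destination; format chosen from the extension.
#' @param quality JPEG quality (ignored for PNG/BMP).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, quality = 95) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bmp") return(write_bmp(img, path))
  stopifnot(ext %in% c("jpg", "jpeg", "png"))
  if (length(dim(img)) == 2) {
    e <- as_ebi(img)
  } else {
    d <- array(0, c(dim(img)[2], dim(img)[1], 3))
    for (k in 1:3) d[, , k] <- t(img[, , k]) / 255
    e <- EBImage::Image(d, colormode = "Color")
  }
  EBImage::writeImage(e, path, quality = quality)
  invisible(path)
}

# Minimal BMP support (BITMAPINFOHEADER, uncompressed, 8-bit palette or
# 24-bit BGR, bottom-up or top-down). No installed R package reads BMP.
read_bmp <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2)
  if (length(magic) < 2 || rawToChar(magic) != "BM")
    bq_stop("bq_format_error", paste(path, "is not a BMP file"))
  readBin(con, "integer", n = 1, size = 4, endian = "little")   # file size
  readBin(con, "raw", n = 4)                                    # reserved
  data_offset <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  hdr_size <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (hdr_size < 40)
    bq_stop("bq_format_error", "unsupported BMP header")
  width <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  height <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  top_down <- height < 0
  height <- abs(height)
  readBin(con, "integer", n = 1, size = 2, endian = "little")   # planes
  bpp <- readBin(con, "integer", n = 1, size = 2, endian = "little")
  compression <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (compression != 0)
    bq_stop("bq_format_error", "compressed BMP is not supported")
  if (!bpp %in% c(8, 24))
    bq_stop("bq_format_error", paste0(bpp, "-bit BMP is not supported"))
  palette <- NULL
  if (bpp == 8) {
    seek(con, 14 + hdr_size)
    n_colors <- (data_offset - 14 - hdr_size) %/% 4
    pal_raw <- readBin(con, "raw", n = n_colors * 4)
    palette <- matrix(as.integer(pal_raw), ncol = 4, byrow = TRUE)  # B,G,R,0
  }
  seek(con, data_offset)
  row_bytes <- ((bpp / 8 * width + 3) %/% 4) * 4
  raw <- readBin(con, "raw", n = row_bytes * height)
  if (length(raw) < row_bytes * height)
    bq_stop("bq_format_error", "truncated BMP pixel data")
  rows <- matrix(as.integer(raw), nrow = row_bytes)  # one column per stored row
  row_order <- if (top_down) seq_len(height) else rev(seq_len(height))
  if (bpp == 8) {
    px <- t(rows[seq_len(width), row_order, drop = FALSE])
    grey_pal <- all(palette[, 1] == palette[, 2] & palette[, 2] == palette[, 3])
    if (grey_pal) {
      matrix(palette[px + 1L, 1], height, width)
    } else {
      out <- array(0L, c(height, width, 3))
      out[, , 1] <- matrix(palette[px + 1L, 3], height, width)
      out[, , 2] <- matrix(palette[px + 1L, 2], height, width)
      out[, , 3] <- matrix(palette[px + 1L, 1], height, width)
      out
    }
  } else {
    out <- array(0L, c(height, width, 3))
    for (k in 1:3) {  # stored B,G,R
      idx <- seq(4 - k, by = 3, length.out = width)
      out[, , k] <- t(rows[idx, row_order, drop = FALSE])
    }
    out
  }
}

write_bmp <- function(img, path) {
  if (length(dim(img)) == 2) {
    h <- nrow(img); w <- ncol(img)
    row_bytes <- ((w + 3) %/% 4) * 4
    data_offset <- 14 + 40 + 256 * 4
    file_size <- data_offset + row_bytes * h
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw("BM"), con)
    writeBin(as.integer(c(file_size)), con, size = 4, endian = "little")
    writeBin(raw(4), con)
    writeBin(as.integer(data_offset), con, size = 4, endian = "little")
    writeBin(as.integer(c(40, w, h)), con, size = 4, endian = "little")
    writeBin(as.integer(c(1, 8)), con, size = 2, endian = "little")
    writeBin(as.integer(c(0, row_bytes * h, 2835, 2835, 256, 0)), con,
             size = 4, endian = "little")
    pal <- as.raw(rep(0:255, each = 4) * c(1, 1, 1, 0))
    writeBin(pal, con)
    pad <- raw(row_bytes - w)
    for (r in h:1) writeBin(c(as.raw(img[r, ]), pad), con)
  } else {
    h <- dim(img)[1]; w <- dim(img)[2]
    row_bytes <- ((3 * w + 3) %/% 4) * 4
    data_offset <- 14 + 40
    file_size <- data_offset + row_bytes * h
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw("BM"), con)
    writeBin(as.integer(file_size), con, size = 4, endian = "little")
    writeBin(raw(4), con)
    writeBin(as.integer(data_offset), con, size = 4, endian = "little")
    writeBin(as.integer(c(40, w, h)), con, size = 4, endian = "little")
    writeBin(as.integer(c(1, 24)), con, size = 2, endian = "little")
    writeBin(as.integer(c(0, row_bytes * h, 2835, 2835, 0, 0)), con,
             size = 4, endian = "little")
    pad <- raw(row_bytes - 3 * w)
    for (r in h:1) {
      bgr <- as.raw(rbind(img[r, , 3], img[r, , 2], img[r, , 1]))
      writeBin(c(bgr, pad), con)
    }
  }
  invisible(path)
}
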