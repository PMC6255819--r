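#' Read a grayscale raster image
#'
#' Reads an 8- or 16-bit single-channel PNG or PGM (P2 ASCII or P5 binary)
#' and maps intensities linearly to `[0, 1]` (8-bit divided by 255, 16-bit
#' by 65535). Multi-channel input is converted by an unweighted luminance
#' average with a warning.
#'
#' @param path File path; format chosen by extension (`.png`, `.pgm`).
#' @return Numeric matrix with values in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("cannot read '%s': no such file", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- tryCatch(png::readPNG(path), error = function(e)
      abort_io(sprintf("cannot read '%s': %s", path, conditionMessage(e))))
    if (length(dim(img)) == 3) {
      warning("multi-channel image converted to grayscale by luminance average")
      img <- apply(img[, , seq_len(min(3, dim(img)[3])), drop = FALSE], c(1, 2), mean)
    }
    img
  } else if (ext == "pgm") {
    read_pgm(path)
  } else {
    abort_io(sprintf("unsupported raster format '.%s' (use PNG or PGM)", ext))
  }
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header tokens: magic, width, height, maxval (comments start with #)
  tokens <- character(0)
  buf <- ""
  while (length(tokens) < 4) {
    ch <- readChar(con, 1, useBytes = TRUE)
    if (!length(ch)) abort_io(sprintf("'%s': truncated PGM header", path))
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1, useBytes = TRUE)
        if (!length(ch) || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[ \t\r\n]", ch)) {
      if (nzchar(buf)) { tokens <- c(tokens, buf); buf <- "" }
    } else buf <- paste0(buf, ch)
  }
  magic <- tokens[1]
  w <- as.integer(tokens[2]); h <- as.integer(tokens[3])
  maxval <- as.integer(tokens[4])
  if (!magic %in% c("P2", "P5") || is.na(w) || is.na(h) || is.na(maxval))
    abort_io(sprintf("'%s': not a valid PGM file", path))
  n <- h * w
  if (magic == "P5") {
    if (maxval < 256) {
      vals <- as.integer(readBin(con, "raw", n))
    } else {
      vals <- readBin(con, "integer", n, size = 2, signed = FALSE, endian = "big")
    }
  } else {
    rest <- readChar(con, file.info(path)$size, useBytes = TRUE)
    vals <- as.integer(strsplit(trimws(rest), "[ \t\r\n]+")[[1]])
  }
  if (length(vals) < n) abort_io(sprintf("'%s': truncated PGM data", path))
  matrix(vals[seq_len(n)] / maxval, h, w, byrow = TRUE)
}

#' Write a grayscale raster image
#'
#' Quantises values in `[0, 1]` linearly (round half up) to the requested
#' bit depth and writes a deterministic file. 8-bit images may be PNG or
#' PGM; 16-bit images are written as binary PGM (P5, big-endian), the
#' preferred depth for synthesis outputs so quantisation does not mask Gram
#' differences. Out-of-range values are an error — nothing is clipped
#' silently.
#'
#' @param image Numeric matrix with values in `[0, 1]`.
#' @param path Output path (`.png` or `.pgm`).
#' @param depth Bits per pixel: 8 or 16.
#' @return The path, invisibly.
#' @export
write_image <- function(image, path, depth = 8L) {
  assert_gray(image)
  if (min(image) < 0 || max(image) > 1)
    abort_input("image values must lie in [0, 1]; refusing to clip silently")
  if (!depth %in% c(8L, 16L)) abort_param("`depth` must be 8 or 16")
  ext <- tolower(tools::file_ext(path))
  maxval <- if (depth == 8L) 255L else 65535L
  q <- round_half_up(image * maxval)
  if (ext == "png") {
    if (depth == 16L)
      abort_param("16-bit output is written as PGM; use a .pgm path")
    png::writePNG(q / 255, path)
  } else if (ext == "pgm") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n%d\n", ncol(image), nrow(image), maxval),
              con, eos = NULL)
    v <- as.integer(t(q)) # row-major per PGM convention
    if (depth == 8L) {
      writeBin(as.raw(v), con)
    } else {
      writeBin(as.raw(rbind(v %/% 256L, v %% 256L)), con) # big-endian 16-bit
    }
  } else {
    abort_io(sprintf("unsupported raster format '.%s' (use PNG or PGM)", ext))
  }
  invisible(path)
}
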