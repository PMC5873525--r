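# Plain-text image I/O.  Micrographs are exchanged as portable graymaps
# (PGM): P2 (ASCII) is written, P2 and P5 (binary) are read.  PGM keeps
# fixtures human-readable and diff-able; TIFF export from the microscope
# should be converted upstream (e.g. ImageMagick `convert img.tif img.pgm`).

#' Read a grayscale image from a PGM file
#'
#' @param path file path to a P2 (ASCII) or P5 (binary, maxval <= 255) PGM.
#' @return Integer matrix (rows = y, top row first) with attribute
#'   `"maxval"`.
#' @export
read_pgm <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  if (!magic %in% c("P2", "P5")) {
    stop("not a PGM file (magic ", magic, "): ", path, call. = FALSE)
  }
  # token reader skipping whitespace and '#' comments
  read_token <- function() {
    tok <- character(0)
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) break
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (length(tok) > 0L) break else next
      }
      tok <- c(tok, ch)
    }
    paste(tok, collapse = "")
  }
  hdr <- suppressWarnings(as.integer(c(read_token(), read_token(),
                                       read_token())))
  if (anyNA(hdr) || any(hdr <= 0)) {
    stop("malformed PGM header: ", path, call. = FALSE)
  }
  nx <- hdr[1]; ny <- hdr[2]; maxval <- hdr[3]
  n <- nx * ny
  vals <- if (magic == "P5") {
    if (maxval > 255L) stop("16-bit binary PGM not supported", call. = FALSE)
    as.integer(readBin(con, "raw", n))
  } else {
    txt <- sub("#.*", "", readLines(con, warn = FALSE))
    tok <- unlist(strsplit(paste(txt, collapse = " "), "[[:space:]]+"))
    as.integer(tok[nzchar(tok)])[seq_len(n)]
  }
  if (length(vals) != n || anyNA(vals)) {
    stop("truncated or malformed PGM raster: ", path, call. = FALSE)
  }
  img <- matrix(vals, nrow = ny, ncol = nx, byrow = TRUE)
  attr(img, "maxval") <- maxval
  img
}

#' Write a grayscale image as ASCII PGM (P2)
#'
#' @param image integer matrix (rows = y).
#' @param path output file path.
#' @param maxval maximum gray level declared in the header.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(image, path, maxval = 255L) {
  stopifnot(is.matrix(image), all(image >= 0), all(image <= maxval))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(image), nrow(image)), as.character(maxval)),
             con)
  apply(image, 1L, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}
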