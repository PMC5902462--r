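# Image I/O. The deployment environment provides no TIFF/PNG codec for R, so
# images travel as NetPBM PGM (P5 binary by default, P2 ASCII on request) --
# readable by ImageJ, scikit-image, ffmpeg and most viewers. Movies are
# concatenated P5 frames in a single file (the multi-frame convention ffmpeg
# and ImageJ import as an image sequence).

#' Write a grayscale image as PGM
#'
#' @param image numeric matrix; values are clamped to `[0, maxval]` and
#'   rounded.
#' @param path output file.
#' @param maxval maximum grey value (<= 255).
#' @param ascii write plain-text P2 instead of binary P5.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(image, path, maxval = 255L, ascii = FALSE) {
  stopifnot(is.matrix(image), maxval >= 1, maxval <= 255)
  v <- pmin(pmax(round(t(image)), 0), maxval)  # PGM is row-major
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(image), nrow(image)), as.character(maxval)), con)
    write(as.integer(v), con, ncolumns = 16L)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n%d\n", ncol(image), nrow(image), maxval),
              con, eos = NULL)
    writeBin(as.raw(as.integer(v)), con)
  }
  invisible(path)
}

#' Write a movie as concatenated PGM frames
#'
#' @param stack numeric array `rows x cols x frames`.
#' @param path output file.
#' @param maxval maximum grey value.
#' @return `path`, invisibly.
#' @export
write_pgm_movie <- function(stack, path, maxval = 255L) {
  stopifnot(length(dim(stack)) == 3)
  con <- file(path, "wb")
  on.exit(close(con))
  nr <- dim(stack)[1]; nc <- dim(stack)[2]
  for (f in seq_len(dim(stack)[3])) {
    writeChar(sprintf("P5\n%d %d\n%d\n", nc, nr, maxval), con, eos = NULL)
    v <- pmin(pmax(round(t(stack[, , f])), 0), maxval)
    writeBin(as.raw(as.integer(v)), con)
  }
  invisible(path)
}

# Read one PGM image (P2 or P5) from an open binary connection; NULL at EOF.
.read_pgm_one <- function(con) {
  tok <- character()
  # header tokens: magic, width, height, maxval (comments skipped)
  while (length(tok) < 4) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0 || !nzchar(ch)) {
      if (length(tok) == 0) return(NULL)
      stop("truncated PGM header")
    }
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (!length(ch) || ch == "\n") break
      }
    } else if (grepl("[[:space:]]", ch)) {
      next
    } else {
      word <- ch
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (!length(ch) || grepl("[[:space:]]", ch)) break
        word <- paste0(word, ch)
      }
      tok <- c(tok, word)
    }
  }
  magic <- tok[1]
  w <- as.integer(tok[2]); h <- as.integer(tok[3]); maxval <- as.integer(tok[4])
  if (!magic %in% c("P2", "P5")) stop("unsupported PGM magic: ", magic)
  n <- w * h
  if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", n))
    if (length(vals) < n) stop("truncated PGM data")
  } else {
    vals <- integer(0)
    while (length(vals) < n) {
      more <- scan(con, what = integer(), n = n - length(vals), quiet = TRUE)
      if (!length(more)) stop("truncated PGM data")
      vals <- c(vals, more)
    }
  }
  matrix(as.numeric(vals), nrow = h, ncol = w, byrow = TRUE)
}

#' Read a PGM image (single frame)
#'
#' @param path PGM file (P2 or P5).
#' @return numeric matrix of grey values.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  img <- .read_pgm_one(con)
  if (is.null(img)) stop("empty PGM file: ", path)
  img
}

#' Read a multi-frame PGM movie
#'
#' @param path file of concatenated PGM frames.
#' @return numeric array `rows x cols x frames`.
#' @export
read_pgm_movie <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  frames <- list()
  repeat {
    img <- .read_pgm_one(con)
    if (is.null(img)) break
    frames[[length(frames) + 1L]] <- img
  }
  if (!length(frames)) stop("empty PGM movie: ", path)
  array(unlist(frames), dim = c(nrow(frames[[1]]), ncol(frames[[1]]),
                                length(frames)))
}
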