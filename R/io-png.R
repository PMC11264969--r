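# 16-bit grayscale PNG export.
#
# Written from first principles on top of base R's zlib bindings
# (memCompress emits an RFC-1950 zlib stream, exactly what a PNG IDAT chunk
# holds); chunk CRC-32 is computed with a table-driven implementation. The
# installed png package writes 8-bit only, and particle images need the full
# 16-bit dynamic range.

.pngEnv <- new.env(parent = emptyenv())

crc32Table <- function() {
  if (is.null(.pngEnv$tab)) {
    tab <- integer(256L)
    for (i in 0:255) {
      c <- i
      for (k in 1:8) {
        c <- if (bitwAnd(c, 1L) != 0L) {
          bitwXor(-306674912L, bitwShiftR(bitwAnd(c, -2L), 1L))  # 0xEDB88320
        } else bitwShiftR(bitwAnd(c, -2L), 1L)
      }
      tab[i + 1L] <- c
    }
    .pngEnv$tab <- tab
  }
  .pngEnv$tab
}

crc32 <- function(bytes) {
  tab <- crc32Table()
  c <- -1L  # 0xFFFFFFFF
  for (b in as.integer(bytes)) {
    idx <- bitwAnd(bitwXor(c, b), 255L)
    c <- bitwXor(tab[idx + 1L], bitwShiftR(bitwAnd(c, -256L), 8L))
  }
  bitwXor(c, -1L)
}

uint32be <- function(x) {
  x <- as.numeric(x) %% 4294967296
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

pngChunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  crc <- crc32(body)
  c(uint32be(length(data)), body, uint32be(if (crc < 0) crc + 4294967296 else crc))
}

# Write a matrix of integers in [0, 65535] as a 16-bit grayscale PNG.
writePng16 <- function(vals, path) {
  h <- nrow(vals); w <- ncol(vals)
  v <- as.integer(round(t(vals)))            # row-major scanlines
  hi <- v %/% 256L; lo <- v %% 256L
  sl <- matrix(0L, nrow = 2L * w + 1L, ncol = h)
  sl[2L * seq_len(w), ] <- matrix(hi, w, h)
  sl[2L * seq_len(w) + 1L, ] <- matrix(lo, w, h)  # filter byte 0 leads each row
  raw_data <- as.raw(as.vector(sl))
  ihdr <- c(uint32be(w), uint32be(h), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           pngChunk("IHDR", ihdr),
           pngChunk("IDAT", memCompress(raw_data, type = "gzip")),
           pngChunk("IEND", raw(0L)))
  writeBin(out, path)
  invisible(path)
}

#' Export a stack as 16-bit grayscale PNG files
#'
#' One PNG per image, each linearly rescaled so that its own minimum maps to
#' 0 and its maximum to 65535 (per-image scaling maximises usable dynamic
#' range for contrast-sensitive preprocessing); a constant image maps to all
#' zeros. Files are named by ascending zero-padded stack index so that
#' downstream classification output can be indexed by filename.
#'
#' @param stack a [ParticleStack-class].
#' @param dir output directory (created if missing).
#' @return character vector of file paths, in stack order (which is also
#'   ascending filename order).
#' @export
exportPng16 <- function(stack, dir) {
  stopifnot(methods::is(stack, "ParticleStack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nz <- nImages(stack)
  paths <- file.path(dir, sprintf("%06d.png", seq_len(nz)))
  for (k in seq_len(nz)) {
    img <- stack@images[, , k]
    rng <- range(img)
    vals <- if (rng[2L] > rng[1L]) {
      (img - rng[1L]) / (rng[2L] - rng[1L]) * 65535
    } else {
      matrix(0, nrow(img), ncol(img))
    }
    writePng16(vals, paths[k])
  }
  paths
}
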