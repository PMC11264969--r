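# MRC / MRCS stack reader and writer.
#
# The on-disk layout follows the MRC2014 convention: a 1024-byte header
# (56 4-byte words + ten 80-character labels), x the fastest axis, one
# section per particle image. Stacks are written as 32-bit float (mode 2),
# the lingua franca of cryo-EM tools; integer gray modes (0, 1, 6) are
# promoted to double on read.

.mrcModes <- c(`0` = "int8", `1` = "int16", `2` = "float32", `6` = "uint16")

#' Read a particle stack from an MRC/MRCS file
#'
#' @param path path to an existing MRC or MRCS file.
#' @return a [ParticleStack-class]; images are ordered as stored, ids are
#'   zero-padded frame indices (ascending).
#' @details The frame count is \code{nz}; each section must be square with an
#'   even side (required by the \code{(n/2) x 360} polar transform of the
#'   alignment stage). Little-endian files only (the only variant the writer
#'   emits and the overwhelmingly common one).
#' @examples
#' f <- tempfile(fileext = ".mrcs")
#' writeParticles(ParticleStack(array(rnorm(16 * 16 * 2), c(16, 16, 2))), f)
#' nImages(readParticles(f))
#' @export
readParticles <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", n = 56, size = 4L, endian = "little")
  nx <- hdr[1L]; ny <- hdr[2L]; nz <- hdr[3L]; mode <- hdr[4L]
  # words 11..13 (cell size in Angstrom) and 50..52 (origin) are floats
  seek(con, 4L * 10L)
  cella <- readBin(con, "double", n = 3, size = 4L, endian = "little")
  seek(con, 4L * 52L)
  map <- readBin(con, "raw", n = 4L)
  if (!identical(map[1:3], charToRaw("MAP"))) {
    stop("format error: not an MRC file (missing MAP magic): ", path)
  }
  if (!(as.character(mode) %in% names(.mrcModes))) {
    stop("format error: unsupported MRC mode ", mode)
  }
  if (nx <= 0L || ny <= 0L || nz <= 0L) {
    stop("format error: non-positive dimensions in MRC header")
  }
  if (nx != ny) stop("dimension error: images must be square, got ",
                     nx, " x ", ny)
  if (nx %% 2L != 0L) stop("dimension error: image side must be even, got ", nx)
  mx <- hdr[8L]
  ps <- if (mx > 0L && cella[1L] > 0) signif(cella[1L] / mx, 7L) else 1
  seek(con, 1024L + hdr[24L])   # skip extended header (nsymbt bytes)
  npix <- as.numeric(nx) * ny * nz
  vals <- switch(as.character(mode),
    `0` = as.double(readBin(con, "integer", n = npix, size = 1L,
                            signed = TRUE, endian = "little")),
    `1` = as.double(readBin(con, "integer", n = npix, size = 2L,
                            signed = TRUE, endian = "little")),
    `2` = readBin(con, "double", n = npix, size = 4L, endian = "little"),
    `6` = {
      v <- readBin(con, "integer", n = npix, size = 2L, signed = FALSE,
                   endian = "little")
      as.double(v)
    })
  if (length(vals) != npix) stop("format error: truncated MRC data")
  # stored x-fastest: section k is matrix(nx, ny); transpose to [row=y, col=x]
  a <- array(vals, c(nx, ny, nz))
  a <- aperm(a, c(2L, 1L, 3L))
  ParticleStack(a, pixelSize = ps)
}

#' Write a particle stack to an MRC/MRCS file
#'
#' Writes a multi-frame 32-bit float (mode 2) stack with a standard 1024-byte
#' header; the pixel size is stored through the cell dimension so that
#' \code{readParticles} recovers it.
#'
#' @param stack a [ParticleStack-class] with at least one image.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeParticles <- function(stack, path) {
  stopifnot(methods::is(stack, "ParticleStack"))
  if (nImages(stack) < 1L) stop("refusing to write a zero-image stack")
  n <- imageSide(stack); nz <- nImages(stack)
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot open for writing: ", path))
  on.exit(close(con))
  ints <- integer(56)
  ints[1:3] <- c(n, n, nz)      # nx ny nz
  ints[4L] <- 2L                # mode 2 = float32
  ints[8:10] <- c(n, n, nz)     # mx my mz
  ints[17:19] <- c(1L, 2L, 3L)  # mapc mapr maps
  writeBin(ints[1:10], con, size = 4L, endian = "little")
  writeBin(c(pixelSize(stack) * c(n, n, nz), 90, 90, 90), con, size = 4L,
           endian = "little")                       # cella, cellb
  writeBin(ints[17:19], con, size = 4L, endian = "little")
  rng <- range(stack@images)
  writeBin(c(rng[1L], rng[2L], mean(stack@images)), con, size = 4L,
           endian = "little")                       # dmin dmax dmean
  writeBin(integer(27), con, size = 4L, endian = "little")  # ispg, nsymbt, extra
  writeBin(numeric(3), con, size = 4L, endian = "little")   # origin
  writeBin(charToRaw("MAP "), con)
  writeBin(c(0x44L, 0x44L, 0x00L, 0x00L), con, size = 1L)   # little-endian
  writeBin(stats::sd(stack@images), con, size = 4L, endian = "little")
  writeBin(1L, con, size = 4L, endian = "little")           # nlabl
  lab <- sprintf("%-80s", "cryoclass particle stack")
  writeBin(charToRaw(lab), con)
  writeBin(raw(800L - 80L), con)
  writeBin(as.vector(aperm(stack@images, c(2L, 1L, 3L))), con, size = 4L,
           endian = "little")
  invisible(path)
}

# Round doubles through 4-byte float storage (what writing to MRC does);
# useful for exact roundtrip comparisons.
#' @rdname writeParticles
#' @param x numeric vector/array to round through 32-bit float precision.
#' @export
asFloat32 <- function(x) {
  d <- dim(x)
  con <- rawConnection(raw(0L), "wb")
  writeBin(as.vector(x), con, size = 4L)
  r <- rawConnectionValue(con)
  close(con)
  y <- readBin(r, "double", n = length(x), size = 4L)
  if (!is.null(d)) dim(y) <- d
  y
}
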