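#' ParticleStack: an ordered stack of square particle images
#'
#' The central data container of the package: a set of square, single-channel
#' float images (particles or class averages) with a physical pixel size and
#' stable per-image identifiers. Images are stored as an \code{n x n x N}
#' numeric array; identifiers are unique and kept in ascending lexicographic
#' order so that on-disk exports can be indexed by filename.
#'
#' The side length \code{n} must be even: the polar Fourier transform used by
#' the alignment stage samples \code{n/2} radii.
#'
#' @slot images numeric array \code{n x n x N}, arbitrary units.
#' @slot pixelSize physical pixel size in Angstrom per pixel.
#' @slot ids character vector of \code{N} unique, sorted identifiers.
#'
#' @seealso [ParticleStack()], [readParticles()], [writeParticles()]
#' @export
setClass("ParticleStack",
  representation(
    images    = "array",
    pixelSize = "numeric",
    ids       = "character"
  )
)

setValidity("ParticleStack", function(object) {
  d <- dim(object@images)
  if (length(d) != 3L) {
    return("images must be an n x n x N array")
  }
  if (d[1L] != d[2L]) {
    return(sprintf("images must be square (got %d x %d)", d[1L], d[2L]))
  }
  if (d[1L] %% 2L != 0L) {
    return(sprintf("image side must be even (got %d)", d[1L]))
  }
  if (d[3L] < 1L) {
    return("a stack must hold at least one image")
  }
  if (!is.numeric(object@images) || anyNA(object@images)) {
    return("images must be numeric with no missing values")
  }
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0) {
    return("pixelSize must be a single positive number")
  }
  if (length(object@ids) != d[3L]) {
    return("length(ids) must equal the number of images")
  }
  if (anyDuplicated(object@ids)) {
    return("ids must be unique")
  }
  if (is.unsorted(object@ids)) {
    return("ids must be in ascending lexicographic order")
  }
  TRUE
})

#' Construct a ParticleStack
#'
#' @param images an \code{n x n x N} array, a single \code{n x n} matrix, or a
#'   list of equally sized square matrices.
#' @param pixelSize pixel size in Angstrom per pixel (default 1).
#' @param ids optional identifiers; by default zero-padded decimal indices
#'   (\code{"000001"}, ...) which sort ascending. If supplied, images are
#'   reordered so that ids are ascending.
#' @return a [ParticleStack-class] object.
#' @examples
#' ps <- ParticleStack(array(rnorm(16 * 16 * 3), c(16, 16, 3)), pixelSize = 1.34)
#' nImages(ps)
#' @export
ParticleStack <- function(images, pixelSize = 1, ids = NULL) {
  if (is.list(images)) {
    if (length(images) == 0L) stop("empty image list")
    d1 <- dim(images[[1L]])
    images <- array(unlist(images, use.names = FALSE),
                    c(d1[1L], d1[2L], length(images)))
  }
  if (is.matrix(images)) images <- array(images, c(dim(images), 1L))
  n3 <- dim(images)[3L]
  if (is.null(ids)) {
    ids <- formatC(seq_len(n3), width = max(6L, nchar(n3)), flag = "0")
  } else {
    ids <- as.character(ids)
    o <- order(ids, method = "radix")
    images <- images[, , o, drop = FALSE]
    ids <- ids[o]
  }
  storage.mode(images) <- "double"
  methods::new("ParticleStack", images = images, pixelSize = pixelSize,
               ids = ids)
}

#' EmbeddingSet: learned particle features
#'
#' Holds the backbone features \code{h} (one 512-dimensional row per image),
#' the L2-normalised projected features \code{z} (128-dimensional rows), and
#' an optional table of each sample's K nearest neighbours by cosine
#' similarity of \code{z}.
#'
#' @slot h numeric matrix, N x 512 backbone features.
#' @slot z numeric matrix, N x 128 unit-norm projected features.
#' @slot neighbors integer matrix N x K of neighbour row indices (0 columns
#'   until [mineNeighbors()] is run).
#' @slot ids character identifiers matching the source stack.
#' @export
setClass("EmbeddingSet",
  representation(h = "matrix", z = "matrix", neighbors = "matrix",
                 ids = "character")
)

setValidity("EmbeddingSet", function(object) {
  n <- nrow(object@h)
  if (nrow(object@z) != n) return("h and z must have the same row count")
  if (length(object@ids) != n) return("ids must match the row count")
  if (nrow(object@neighbors) != n && ncol(object@neighbors) > 0L) {
    return("neighbor table must have one row per sample")
  }
  if (ncol(object@neighbors) > 0L) {
    k <- object@neighbors
    if (any(k < 1L | k > n)) return("neighbor indices out of range")
    if (any(k == row(k))) return("neighbor table must not contain self-indices")
  }
  TRUE
})

#' EncoderModel: contrastive (pretext) encoder
#'
#' The stage-1 model: a residual convolutional backbone \code{f} producing a
#' 512-dimensional feature \code{h}, and a 2-layer perceptron projection head
#' \code{g} producing a unit-norm 128-dimensional feature \code{z} used by the
#' instance-discrimination loss. After training, \code{g} is kept only so
#' that \code{z} features can be recomputed; downstream stages consume
#' \code{h} through the clustering head.
#'
#' @slot backbone internal network object (list of layer environments).
#' @slot head internal projection-head network object.
#' @slot inputSize network input side length in pixels.
#' @slot temperature softmax temperature of the contrastive loss.
#' @slot lossCurve numeric, mean training loss per epoch.
#' @slot knnCurve numeric, per-epoch KNN validation accuracy (may be empty).
#' @slot trained logical flag.
#' @slot seed integer seed the model was trained with.
#' @export
setClass("EncoderModel",
  representation(backbone = "list", head = "list", inputSize = "integer",
                 temperature = "numeric", lossCurve = "numeric",
                 knnCurve = "numeric", trained = "logical", seed = "integer")
)

#' ClusterModel: neighbour-consistency clustering head over a pretext encoder
#'
#' The stage-2 model: the pretext backbone plus a linear layer mapping the
#' 512-dimensional feature to C logits; a softmax turns these into the class
#' probability vector used for assignment, pseudo-labelling and class-average
#' weights.
#'
#' @slot backbone internal network object (initialised from stage 1).
#' @slot headLayer internal linear layer 512 -> C.
#' @slot nClasses number of clusters C.
#' @slot inputSize network input side length in pixels.
#' @slot lossCurve numeric, mean training loss per epoch.
#' @slot trained logical flag.
#' @slot seed integer seed.
#' @export
setClass("ClusterModel",
  representation(backbone = "list", headLayer = "list", nClasses = "integer",
                 inputSize = "integer", lossCurve = "numeric",
                 trained = "logical", seed = "integer")
)

#' DenoiserModel: adversarially trained particle denoiser
#'
#' Generator: convolution block, residual blocks, sub-pixel (pixel-shuffle)
#' upsampling block, so input and output shapes are equal. Discriminator: a
#' five-layer convolutional network with batch normalisation and leaky
#' rectifier activations. Trained with an L1 reconstruction loss plus a small
#' adversarial term on paired noisy/clean stacks.
#'
#' @slot generator internal network object.
#' @slot discriminator internal network object.
#' @slot history data.frame of per-epoch reconstruction/adversarial losses.
#' @slot trained logical flag.
#' @slot seed integer seed.
#' @export
setClass("DenoiserModel",
  representation(generator = "list", discriminator = "list",
                 history = "data.frame", trained = "logical", seed = "integer")
)
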