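#' @title Accessors for package classes
#' @description Small accessor generics in the Bioconductor style; slot access
#'   from user code is never needed.
#' @param x an object of a cryoclass S4 class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nImages", function(x) standardGeneric("nImages"))

#' @rdname accessors
#' @export
setGeneric("imageSide", function(x) standardGeneric("imageSide"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("particleIds", function(x) standardGeneric("particleIds"))

#' @rdname accessors
#' @export
setGeneric("getImage", function(x, i) standardGeneric("getImage"))

#' @rdname accessors
#' @export
setGeneric("features", function(x) standardGeneric("features"))

#' @rdname accessors
#' @export
setGeneric("projectedFeatures", function(x) standardGeneric("projectedFeatures"))

#' @rdname accessors
#' @export
setGeneric("neighborTable", function(x) standardGeneric("neighborTable"))

#' @rdname accessors
#' @export
setGeneric("lossCurve", function(x) standardGeneric("lossCurve"))

#' @rdname accessors
#' @export
setGeneric("isTrained", function(x) standardGeneric("isTrained"))

#' @export
#' @rdname accessors
setMethod("nImages", "ParticleStack", function(x) dim(x@images)[3L])

#' @export
#' @rdname accessors
setMethod("imageSide", "ParticleStack", function(x) dim(x@images)[1L])

#' @export
#' @rdname accessors
setMethod("pixelSize", "ParticleStack", function(x) x@pixelSize)

#' @export
#' @rdname accessors
setMethod("particleIds", "ParticleStack", function(x) x@ids)

#' @export
#' @rdname accessors
setMethod("getImage", "ParticleStack", function(x, i) {
  if (is.character(i)) i <- match(i, x@ids)
  x@images[, , i]
})

#' Subset a ParticleStack
#'
#' @param x a [ParticleStack-class].
#' @param i integer, logical or character (id) index.
#' @param j,...,drop ignored.
#' @return a [ParticleStack-class] with the selected images.
#' @export
setMethod("[", "ParticleStack", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@ids)
  ParticleStack(x@images[, , i, drop = FALSE], pixelSize = x@pixelSize,
                ids = x@ids[i])
})

setMethod("show", "ParticleStack", function(object) {
  d <- dim(object@images)
  cat(sprintf("ParticleStack: %d image(s), %d x %d px, %.3g A/px\n",
              d[3L], d[1L], d[2L], object@pixelSize))
  cat(sprintf("  ids: %s%s\n", paste(utils::head(object@ids, 3L),
                                     collapse = ", "),
              if (d[3L] > 3L) ", ..." else ""))
})

#' @export
#' @rdname accessors
setMethod("features", "EmbeddingSet", function(x) x@h)

#' @export
#' @rdname accessors
setMethod("projectedFeatures", "EmbeddingSet", function(x) x@z)

#' @export
#' @rdname accessors
setMethod("neighborTable", "EmbeddingSet", function(x) x@neighbors)

#' @export
#' @rdname accessors
setMethod("particleIds", "EmbeddingSet", function(x) x@ids)

setMethod("show", "EmbeddingSet", function(object) {
  cat(sprintf("EmbeddingSet: %d sample(s), h %d-dim, z %d-dim, %s\n",
              nrow(object@h), ncol(object@h), ncol(object@z),
              if (ncol(object@neighbors) > 0L) {
                sprintf("%d neighbours/sample", ncol(object@neighbors))
              } else "no neighbour table"))
})

#' @export
#' @rdname accessors
setMethod("lossCurve", "EncoderModel", function(x) x@lossCurve)

#' @export
#' @rdname accessors
setMethod("lossCurve", "ClusterModel", function(x) x@lossCurve)

#' @export
#' @rdname accessors
setMethod("isTrained", "EncoderModel", function(x) x@trained)

#' @export
#' @rdname accessors
setMethod("isTrained", "ClusterModel", function(x) x@trained)

#' @export
#' @rdname accessors
setMethod("isTrained", "DenoiserModel", function(x) x@trained)

setMethod("show", "EncoderModel", function(object) {
  cat(sprintf("EncoderModel (contrastive pretext): input %dx%d, tau=%.2f, %s\n",
              object@inputSize, object@inputSize, object@temperature,
              if (object@trained) {
                sprintf("trained %d epoch(s), final loss %.4f",
                        length(object@lossCurve),
                        utils::tail(object@lossCurve, 1L))
              } else "untrained"))
})

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf("ClusterModel: %d classes, input %dx%d, %s\n",
              object@nClasses, object@inputSize, object@inputSize,
              if (object@trained) {
                sprintf("trained %d epoch(s)", length(object@lossCurve))
              } else "untrained"))
})

setMethod("show", "DenoiserModel", function(object) {
  cat(sprintf("DenoiserModel (adversarial): %s\n",
              if (object@trained) {
                sprintf("trained %d epoch(s), final L1 %.5f",
                        nrow(object@history),
                        utils::tail(object@history$recon, 1L))
              } else "untrained"))
})
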