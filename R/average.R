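# Probability-weighted class averaging: members of a class are combined
# with weights proportional to their softmax class probability, instead of
# a plain mean, so confidently assigned particles dominate the average.

#' Normalise member probabilities into averaging weights
#'
#' \code{w_i = p_i / sum(p)}; all probabilities must lie in (0, 1], all
#' weights lie in [0, 1] and sum to 1.
#'
#' @param probs per-member maximum softmax probabilities.
#' @return numeric weight vector.
#' @export
classWeights <- function(probs) {
  if (length(probs) == 0L) stop("empty probability list")
  if (any(!is.finite(probs)) || any(probs <= 0) || any(probs > 1)) {
    stop("probabilities must lie in (0, 1]")
  }
  probs / sum(probs)
}

#' Weighted average of aligned class members
#'
#' Pixelwise \code{sum_i w_i * I_i}; with uniform weights this is exactly
#' the arithmetic mean. Averaging m aligned members with independent noise
#' reduces the residual noise variance roughly m-fold.
#'
#' @param aligned a [ParticleStack-class] of aligned members.
#' @param weights numeric weights, one per member, summing to 1 (within
#'   1e-6); see [classWeights()].
#' @return list: \code{average} (matrix), \code{weights}, \code{ids}.
#' @export
weightedAverage <- function(aligned, weights) {
  m <- nImages(aligned)
  if (length(weights) != m) stop("one weight per member required")
  if (abs(sum(weights) - 1) > 1e-6) stop("weights must sum to 1")
  n <- imageSide(aligned)
  avg <- matrix(0, n, n)
  for (k in seq_len(m)) avg <- avg + weights[k] * aligned@images[, , k]
  list(average = avg, weights = weights, ids = particleIds(aligned))
}

#' Aligned, probability-weighted class averages for a clustering result
#'
#' For every cluster: members are aligned to the highest-probability member
#' (see [alignClass()]), weighted by their class probability and averaged.
#' Classes are returned sorted by decreasing mean member probability.
#'
#' @param stack the full [ParticleStack-class].
#' @param assignments data.frame from [assignClusters()].
#' @param align align members before averaging (default TRUE; disable for
#'   pre-aligned input).
#' @param uniformWeights use uniform instead of probability weights (an
#'   ablation switch).
#' @param minMembers clusters smaller than this are skipped.
#' @return list: \code{averages} (a [ParticleStack-class], one frame per
#'   class, ids \code{"class_<k>"} in sorted order), \code{summary}
#'   (data.frame: class, members, meanProb).
#' @export
classAverages <- function(stack, assignments, align = TRUE,
                          uniformWeights = FALSE, minMembers = 2L) {
  stopifnot(all(c("id", "label", "prob") %in% names(assignments)))
  classes <- sort(unique(assignments$label))
  avgs <- list(); rows <- list()
  for (cl in classes) {
    mem <- assignments[assignments$label == cl, ]
    if (nrow(mem) < minMembers) next
    sub <- stack[mem$id]
    mem <- mem[match(particleIds(sub), mem$id), ]
    if (align) {
      refIdx <- which.max(mem$prob)
      al <- alignClass(sub, refIdx = refIdx)
      sub <- al$aligned
      mem <- mem[match(particleIds(sub), mem$id), ]
    }
    w <- if (uniformWeights) {
      rep(1 / nrow(mem), nrow(mem))
    } else {
      classWeights(mem$prob)
    }
    wa <- weightedAverage(sub, w)
    avgs[[as.character(cl)]] <- wa$average
    rows[[as.character(cl)]] <- data.frame(class = cl,
                                           members = nrow(mem),
                                           meanProb = mean(mem$prob))
  }
  if (!length(avgs)) stop("no cluster has enough members")
  summary <- do.call(rbind, rows)
  o <- order(-summary$meanProb)
  summary <- summary[o, ]
  rownames(summary) <- NULL
  ids <- sprintf("class_%03d_rank%02d", summary$class, seq_len(nrow(summary)))
  list(averages = ParticleStack(avgs[as.character(summary$class)],
                                pixelSize = pixelSize(stack), ids = ids),
       summary = summary)
}

#' Peak signal-to-noise ratio against a clean reference
#'
#' \code{10 log10(peak^2 / MSE)} with peak the dynamic range of the clean
#' image; the standard oracle for denoiser quality on simulated pairs.
#'
#' @param img image under test.
#' @param clean reference image.
#' @return PSNR in dB.
#' @export
psnr <- function(img, clean) {
  peak <- diff(range(clean))
  mse <- mean((img - clean)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}
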