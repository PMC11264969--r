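# Clustering evaluation: Hungarian-matched accuracy, pairwise
# Fowlkes-Mallows index, normalised mutual information, and the metrics
# report. All metrics are invariant under relabelling of either partition.

# Kuhn-Munkres (Hungarian) minimum-cost assignment on a square cost
# matrix; O(n^3) potentials + shortest augmenting paths. Returns, for each
# column, the assigned row. No installed package provides an LSAP solver,
# and the confusion matrices involved are tiny.
hungarianMin <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1L)       # row potentials  (index r+0)
  v <- numeric(n + 1L)       # col potentials  (index c+1; col 0 -> 1)
  p <- integer(n + 1L)       # p[c+1]: row assigned to column c (0 = none)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    way <- integer(n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0L:n) {
        if (used[j + 1L]) {
          u[p[j + 1L]] <- u[p[j + 1L]] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  p[-1L]   # p[c]: row assigned to column c
}

# Maximum-weight one-to-one matching on a (possibly rectangular) weight
# matrix, zero-padded to square. Returns cbind(row, col) over the original
# dimensions.
hungarianMax <- function(w) {
  n <- max(dim(w))
  cost <- matrix(0, n, n)
  cost[seq_len(nrow(w)), seq_len(ncol(w))] <- -w
  rowOfCol <- hungarianMin(cost)
  m <- cbind(row = rowOfCol, col = seq_len(n))
  m[m[, "row"] <= nrow(w) & m[, "col"] <= ncol(w), , drop = FALSE]
}

#' Hungarian-matched clustering accuracy
#'
#' The predicted and true partitions are matched one-to-one on the
#' confusion matrix by the Kuhn-Munkres algorithm (rectangular cases are
#' zero-padded), and the accuracy is the matched sample count over N. Equal
#' partitions score 1 under any relabelling.
#'
#' @param pred,truth equal-length label vectors (any atomic type).
#' @return accuracy in [0, 1].
#' @export
clusteringAccuracy <- function(pred, truth) {
  clusteringMatch(pred, truth)$acc
}

# Accuracy plus the matching and confusion matrix (predicted x true).
clusteringMatch <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  if (length(pred) == 0L) stop("empty partitions")
  conf <- table(pred = as.character(pred), truth = as.character(truth))
  m <- hungarianMax(unclass(conf))
  matched <- sum(conf[m])
  matching <- stats::setNames(colnames(conf)[m[, "col"]],
                              rownames(conf)[m[, "row"]])
  list(acc = matched / length(pred), confusion = conf, matching = matching)
}

#' Pairwise classification counts of two partitions
#'
#' Over all unordered sample pairs: TP = pairs together in both partitions;
#' FP = together in the prediction only; FN = together in the truth only.
#' Computed from the contingency table in O(table size).
#'
#' @param pred,truth equal-length label vectors.
#' @return named numeric vector \code{c(tp, fp, fn)}.
#' @export
pairCounts <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  conf <- table(pred, truth)
  ch2 <- function(x) sum(x * (x - 1) / 2)
  tp <- ch2(conf)
  c(tp = tp, fp = ch2(rowSums(conf)) - tp, fn = ch2(colSums(conf)) - tp)
}

#' Fowlkes-Mallows index
#'
#' \code{FMI = TP / sqrt((TP + FP) * (TP + FN))} on the pairwise counts of
#' [pairCounts()]; defined as 0 when the denominator vanishes (e.g. every
#' sample its own predicted cluster).
#'
#' @param pred,truth equal-length label vectors.
#' @return FMI in [0, 1].
#' @export
fowlkesMallows <- function(pred, truth) {
  pc <- pairCounts(pred, truth)
  den <- sqrt((pc["tp"] + pc["fp"]) * (pc["tp"] + pc["fn"]))
  if (den == 0) return(0)
  unname(pc["tp"] / den)
}

#' Normalised mutual information
#'
#' Mutual information normalised by the geometric mean of the two label
#' entropies (natural logarithms); 0 by convention when either entropy is
#' zero (e.g. a constant prediction).
#'
#' @param pred,truth equal-length label vectors.
#' @return NMI in [0, 1].
#' @export
nmiScore <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  N <- length(pred)
  conf <- table(pred, truth) / N
  pr <- rowSums(conf)
  pt <- colSums(conf)
  h <- function(p) -sum(ifelse(p > 0, p * log(p), 0))
  hr <- h(pr); ht <- h(pt)
  if (hr == 0 || ht == 0) return(0)
  E <- outer(pr, pt)
  mi <- sum(ifelse(conf > 0, conf * log(conf / E), 0))
  max(0, min(1, mi / sqrt(hr * ht)))
}

#' Full clustering metrics report
#'
#' Joins assignments with ground truth by image id and computes ACC
#' (Hungarian-matched), FMI, NMI, the pairwise counts, the confusion matrix
#' and the label matching. Without ground truth the report carries only
#' unsupervised summaries (cluster sizes, mean probabilities).
#'
#' @param assignments data.frame from [assignClusters()] (columns id,
#'   label, prob).
#' @param truth optional data.frame with columns id, class.
#' @param path optional path; when given the report is written as JSON.
#' @return a list (the report), invisibly when \code{path} is given.
#' @export
clusteringReport <- function(assignments, truth = NULL, path = NULL) {
  sizes <- table(assignments$label)
  rep <- list(
    n = nrow(assignments),
    clusterSizes = as.list(stats::setNames(as.integer(sizes), names(sizes))),
    meanProb = mean(assignments$prob),
    pseudoFraction = if ("pseudo" %in% names(assignments)) {
      mean(assignments$pseudo)
    } else NA_real_
  )
  if (!is.null(truth)) {
    i <- match(assignments$id, truth$id)
    if (all(is.na(i))) stop("assignment and truth ids are disjoint")
    ok <- !is.na(i)
    pred <- assignments$label[ok]
    tru <- truth$class[i[ok]]
    cm <- clusteringMatch(pred, tru)
    pc <- pairCounts(pred, tru)
    rep$acc <- cm$acc
    rep$fmi <- fowlkesMallows(pred, tru)
    rep$nmi <- nmiScore(pred, tru)
    rep$tp <- unname(pc["tp"]); rep$fp <- unname(pc["fp"])
    rep$fn <- unname(pc["fn"])
    rep$confusion <- unclass(cm$confusion)
    rep$matching <- as.list(cm$matching)
  }
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         matrix = "rowmajor")
    return(invisible(rep))
  }
  rep
}
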