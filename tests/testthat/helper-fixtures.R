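# Shared fixtures, built once per test run (everything is generated in
# code; nothing is read from disk).

.fixtures <- new.env(parent = emptyenv())

# A 64-px asymmetric phantom and one of its projections.
fixPhantom <- function() {
  if (is.null(.fixtures$phantom)) {
    .fixtures$phantom <- makePhantom(5L, n = 64L, kBlobs = 6L)
  }
  .fixtures$phantom
}

fixProjection <- function() {
  if (is.null(.fixtures$proj)) {
    .fixtures$proj <- projectVolume(fixPhantom(), 40, 60)
  }
  .fixtures$proj
}

# Small labelled random stack (no structure; for IO and plumbing tests).
randomStack <- function(n = 16L, count = 3L, seed = 1L, pixelSize = 1.34) {
  set.seed(seed)
  ParticleStack(array(rnorm(n * n * count), c(n, n, count)),
                pixelSize = pixelSize)
}

randomMetadata <- function(count = 5L, seed = 1L) {
  set.seed(seed)
  data.frame(id = sprintf("%03d", seq_len(count)),
             class = c(0L, seq_len(count - 1L) %% 3L),
             rot = runif(count, 0, 360), tilt = runif(count, 0, 180),
             psi = runif(count, 0, 360), dx = rnorm(count),
             dy = rnorm(count), prob = runif(count), snr = 0.6,
             split = rep(c("train", "val", "test"), length.out = count),
             stringsAsFactors = FALSE)
}

# Random partition labels for metric property tests.
randomPartition <- function(n, k, seed) {
  set.seed(seed)
  sample.int(k, n, replace = TRUE)
}

# Shared tiny trained pipeline for the remaining blocks.
tinyCluster <- function() {
  if (is.null(.fixtures$tinyCluster)) {
    ds <- buildDataset(datasetConfig(nPhantoms = 3L, classes = 1L,
                                     perClass = 20L, snr = 4, seed = 6L))
    proc <- preprocessStack(ds$stack)
    enc <- trainPretext(proc, pretextConfig("desk", epochs = 30L,
                                            batch = 60L, seed = 2L))
    emb <- mineNeighbors(extractFeatures(proc, enc), 5L)
    ccfg <- clusterConfig("desk", nClasses = 3L, epochs = 20L, batch = 30L,
                          seed = 2L)
    cm <- trainCluster(enc, proc, neighborTable(emb), ccfg)
    labels <- ds$metadata$class[match(particleIds(proc), ds$metadata$id)]
    .fixtures$tinyCluster <- list(ds = ds, proc = proc, enc = enc,
                                  emb = emb, cm = cm, ccfg = ccfg,
                                  labels = labels)
  }
  .fixtures$tinyCluster
}

# Logical disc mask: TRUE inside radius frac * n/2 of the image centre.
discMask <- function(n, frac) {
  d <- sqrt(outer((seq_len(n) - (n + 1) / 2)^2,
                  (seq_len(n) - (n + 1) / 2)^2, `+`))
  d < frac * n / 2
}

# Brute-force oracles -------------------------------------------------------

# All-permutation clustering accuracy (<= 6 distinct predicted labels).
accByPermutation <- function(pred, truth) {
  pl <- sort(unique(pred)); tl <- sort(unique(truth))
  k <- max(length(pl), length(tl))
  if (length(pl) > 6L) stop("too many labels for the brute-force oracle")
  tlPad <- c(tl, paste0("pad", seq_len(max(0L, k - length(tl)))))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- 0
  for (p in perms(tlPad)) {
    mapped <- p[match(pred, pl)]
    best <- max(best, mean(mapped == truth))
  }
  best
}

# O(N^2) pair counting.
pairCountsBrute <- function(pred, truth) {
  n <- length(pred)
  tp <- fp <- fn <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sp <- pred[i] == pred[j]
      st <- truth[i] == truth[j]
      if (sp && st) tp <- tp + 1
      if (sp && !st) fp <- fp + 1
      if (!sp && st) fn <- fn + 1
    }
  }
  c(tp = tp, fp = fp, fn = fn)
}

# Loop-based NT-Xent evaluation (rows = 2B embeddings in consecutive pairs).
ntXentBrute <- function(z, tau) {
  m <- nrow(z)
  s <- z %*% t(z) / tau
  tot <- 0
  for (a in seq_len(m)) {
    p <- if (a %% 2L == 1L) a + 1L else a - 1L
    den <- 0
    for (b in seq_len(m)) if (b != a) den <- den + exp(s[a, b])
    tot <- tot - log(exp(s[a, p]) / den)
  }
  tot / m
}

# Loop-based neighbour-consistency loss.
scanLossBrute <- function(pAnchor, pNeighbors, clusterMean, lambda) {
  tot <- 0
  for (p in pNeighbors) tot <- tot - log(max(sum(pAnchor * p), 1e-8))
  ent <- 0
  for (v in clusterMean) if (v > 0) ent <- ent - v * log(v)
  tot / length(pNeighbors) - lambda * ent
}
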