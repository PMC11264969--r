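# Pipeline driver: chains simulate -> preprocess -> (denoise) -> pretext
# -> cluster -> align/average -> evaluate, writing standard artifacts
# (MRCS, STAR/CSV, JSON) at each stage. The command-line wrapper in
# inst/cli/cryoclass.R is a thin shell over these functions.

#' Default pipeline configuration
#'
#' A nested list with one entry per stage; any field can be overridden by
#' the matching entry of the supplied list (or YAML file for the CLI).
#'
#' @param ... named overrides, e.g. \code{dataset = list(classes = 3)}.
#' @return nested configuration list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    dataset = as.list(datasetConfig()),
    preprocess = list(normalize = TRUE, equalize = FALSE, mask = TRUE,
                      radiusFrac = 0.9),
    denoise = list(enabled = FALSE, epochs = 20L, batch = 16L,
                   trainSnr = 0.5),
    pretext = as.list(pretextConfig("desk")),
    neighbors = list(kCluster = 10L, kValidate = 5L),
    cluster = as.list(clusterConfig("desk")),
    average = list(enabled = TRUE, align = TRUE, minMembers = 2L),
    seed = 1L
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  cfg
}

#' Run the full classification pipeline
#'
#' Simulates (or loads) a particle dataset, preprocesses it, trains the
#' contrastive encoder, mines neighbours, trains the clustering head with
#' pseudo-label self-training, computes aligned probability-weighted class
#' averages, and evaluates against the simulation ground truth.
#'
#' @param cfg configuration from [pipelineConfig()].
#' @param outDir optional output directory; when given, every stage writes
#'   its artifacts there.
#' @param stack,metadata optional pre-loaded input data; when omitted the
#'   simulator runs with \code{cfg$dataset}.
#' @param verbose print stage progress.
#' @return list: \code{stack}, \code{metadata}, \code{encoder},
#'   \code{embeddings}, \code{clusterModel}, \code{assignments},
#'   \code{averages} (or NULL), \code{report}.
#' @export
runPipeline <- function(cfg = pipelineConfig(), outDir = NULL,
                        stack = NULL, metadata = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (!is.null(outDir) && !dir.exists(outDir)) {
    dir.create(outDir, recursive = TRUE)
  }
  emit <- function(fn, ...) if (!is.null(outDir)) fn(...)

  cfg$dataset$seed <- childSeed(cfg$seed, 1)
  if (is.null(stack)) {
    say("simulating dataset (%d classes x %d, n=%d, snr=%.2g)",
        cfg$dataset$classes, cfg$dataset$perClass, cfg$dataset$n,
        cfg$dataset$snr)
    ds <- buildDataset(cfg$dataset)
    stack <- ds$stack
    metadata <- ds$metadata
    emit(function() {
      writeParticles(stack, file.path(outDir, "particles.mrcs"))
      writeMetadata(metadata, file.path(outDir, "labels.csv"))
      writeMetadata(metadata, file.path(outDir, "labels.star"))
      jsonlite::write_json(cfg, file.path(outDir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
    })
  }

  say("preprocessing %d images", nImages(stack))
  pp <- cfg$preprocess
  proc <- preprocessStack(stack, normalize = pp$normalize,
                          equalize = pp$equalize, mask = pp$mask,
                          radiusFrac = pp$radiusFrac)
  if (isTRUE(cfg$denoise$enabled)) {
    say("training denoiser (%d epochs)", cfg$denoise$epochs)
    dcfg <- cfg$dataset
    dcfg$snr <- cfg$denoise$trainSnr
    dcfg$seed <- childSeed(cfg$seed, 7)
    noisy <- buildDataset(dcfg)
    cleanCfg <- dcfg; cleanCfg$snr <- Inf
    clean <- buildDataset(cleanCfg)
    den <- trainDenoiser(noisy$stack, clean$stack,
                         epochs = cfg$denoise$epochs,
                         batch = cfg$denoise$batch,
                         seed = childSeed(cfg$seed, 8))
    proc <- denoiseStack(proc, den)
  }
  emit(function() writeParticles(proc, file.path(outDir,
                                                 "preprocessed.mrcs")))

  pcfg <- cfg$pretext
  pcfg$seed <- childSeed(cfg$seed, 2)
  say("pretext training (%d epochs, input %d)", pcfg$epochs,
      pcfg$inputSize)
  pcfg <- do.call(pretextConfig, c(list(preset = "desk"), pcfg))
  encoder <- trainPretext(proc, pcfg, verbose = verbose)
  emb <- extractFeatures(proc, encoder)
  emb <- mineNeighbors(emb, K = cfg$neighbors$kCluster)
  emit(function() {
    utils::write.csv(data.frame(id = particleIds(emb), neighborTable(emb)),
                     file.path(outDir, "neighbors.csv"), row.names = FALSE)
    jsonlite::write_json(list(lossCurve = encoder@lossCurve),
                         file.path(outDir, "metrics_pretext.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  ccfg <- do.call(clusterConfig, c(list(preset = "desk"), cfg$cluster))
  ccfg$seed <- childSeed(cfg$seed, 3)
  say("cluster training (%d classes, %d epochs)", ccfg$nClasses,
      ccfg$epochs)
  cm <- trainCluster(encoder, proc, neighborTable(emb), ccfg,
                     verbose = verbose)
  cm <- selfLabel(cm, proc, threshold = ccfg$threshold, cfg = ccfg,
                  verbose = verbose)
  asg <- assignClusters(cm, proc, threshold = ccfg$threshold)
  emit(function() {
    utils::write.csv(asg, file.path(outDir, "assignments.csv"),
                     row.names = FALSE)
    star <- data.frame(id = asg$id, class = asg$label, prob = asg$prob)
    writeMetadata(star, file.path(outDir, "assignments.star"))
  })

  averages <- NULL
  if (isTRUE(cfg$average$enabled)) {
    say("aligned class averaging")
    averages <- tryCatch(
      classAverages(stack, asg, align = cfg$average$align,
                    minMembers = cfg$average$minMembers),
      error = function(e) {
        warning("class averaging skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(averages)) {
      emit(function() {
        writeParticles(averages$averages,
                       file.path(outDir, "class_averages.mrcs"))
        utils::write.csv(averages$summary,
                         file.path(outDir, "class_summary.csv"),
                         row.names = FALSE)
      })
    }
  }

  truth <- if (!is.null(metadata) && "class" %in% names(metadata)) {
    metadata[, c("id", "class")]
  } else NULL
  report <- clusteringReport(asg, truth,
                             path = if (!is.null(outDir)) {
                               file.path(outDir, "metrics.json")
                             } else NULL)
  if (!is.null(truth)) say("ACC %.3f  FMI %.3f  NMI %.3f", report$acc,
                           report$fmi, report$nmi)
  list(stack = stack, metadata = metadata, encoder = encoder,
       embeddings = emb, clusterModel = cm, assignments = asg,
       averages = averages, report = report)
}

#' Save / load a trained model
#'
#' Thin RDS-based checkpointing for the S4 model objects (layer
#' environments serialise cleanly).
#'
#' @param model any model object.
#' @param path checkpoint path.
#' @return \code{loadModel} returns the model.
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) readRDS(path)
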