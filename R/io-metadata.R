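# Particle metadata tables: CSV and a STAR mirror.
#
# A metadata table is a plain data.frame keyed by image id with the columns
#   id    character, must match the paired stack's ids
#   class integer cluster/ground-truth label (>= 0) or NA
#   rot, tilt, psi   projection/in-plane angles in degrees
#   dx, dy           origin shifts in pixels (positive right/down)
#   prob  assignment probability in [0, 1] (optional)
#   snr   simulated signal-to-noise ratio (optional)
#   split "train" / "val" / "test" (optional)
# The STAR dialect is a single particles loop using conventional label names
# so the files load in standard viewers; the CSV mirrors it 1:1.

.starLabels <- c(
  id    = "_rlnImageName",
  class = "_rlnClassNumber",
  rot   = "_rlnAngleRot",
  tilt  = "_rlnAngleTilt",
  psi   = "_rlnAnglePsi",
  dx    = "_rlnOriginX",
  dy    = "_rlnOriginY",
  prob  = "_rlnMaxValueProbDistribution",
  snr   = "_ccSnr",
  split = "_ccSplit"
)
.metaNumeric <- c("rot", "tilt", "psi", "dx", "dy", "prob", "snr")

#' Validate a particle metadata table
#'
#' @param table a data.frame with at least an \code{id} column.
#' @param stack optional [ParticleStack-class]; when given, every id in the
#'   table must exist in the stack.
#' @return the table, invisibly, with canonical column types.
#' @export
validateMetadata <- function(table, stack = NULL) {
  if (!is.data.frame(table) || !"id" %in% names(table)) {
    stop("metadata must be a data.frame with an 'id' column")
  }
  table$id <- as.character(table$id)
  if (anyDuplicated(table$id)) stop("validation error: duplicate ids")
  if ("class" %in% names(table)) {
    cl <- table$class
    if (any(!is.na(cl) & (cl < 0 | cl != floor(cl)))) {
      stop("validation error: class labels must be integers >= 0 or missing")
    }
    table$class <- as.integer(cl)
  }
  for (cn in intersect(.metaNumeric, names(table))) {
    table[[cn]] <- as.numeric(table[[cn]])
    if (cn %in% c("rot", "tilt", "psi") && any(!is.finite(table[[cn]]))) {
      stop("validation error: angles must be finite")
    }
  }
  if ("prob" %in% names(table)) {
    p <- table$prob
    if (any(!is.na(p) & (p < 0 | p > 1))) {
      stop("validation error: probabilities must lie in [0, 1]")
    }
  }
  if (!is.null(stack)) {
    missing <- setdiff(table$id, particleIds(stack))
    if (length(missing)) {
      stop("validation error: ids absent from the paired stack: ",
           paste(utils::head(missing, 5L), collapse = ", "))
    }
  }
  invisible(table)
}

#' Read a particle metadata table (CSV or STAR)
#'
#' The dialect is chosen by file extension: \code{.star} parses a single
#' particles loop; anything else is read as CSV. Both dialects produce the
#' same table.
#'
#' @param path input file.
#' @return a validated data.frame (see [validateMetadata()]).
#' @export
readMetadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- if (grepl("\\.star$", path, ignore.case = TRUE)) {
    readStarLoop(path)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(id = "character"))
  }
  validateMetadata(tab)
  tab
}

#' Write a particle metadata table (CSV or STAR)
#'
#' @param table a metadata data.frame.
#' @param path output file; a \code{.star} extension selects the STAR
#'   dialect, anything else CSV.
#' @return invisibly, \code{path}.
#' @export
writeMetadata <- function(table, path) {
  table <- validateMetadata(table)
  if (grepl("\\.star$", path, ignore.case = TRUE)) {
    writeStarLoop(table, path)
  } else {
    utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

readStarLoop <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  li <- which(lines == "loop_")
  if (!length(li)) stop("format error: no loop_ block in STAR file")
  body <- lines[(li[1L] + 1L):length(lines)]
  isLab <- startsWith(body, "_")
  labs <- sub("\\s+#\\d+$", "", body[isLab])
  rows <- body[!isLab]
  rows <- rows[!startsWith(rows, "data_")]
  fields <- strsplit(rows, "\\s+")
  bad <- vapply(fields, length, 1L) != length(labs)
  if (any(bad)) stop("format error: STAR row/label count mismatch")
  m <- do.call(rbind, fields)
  tab <- as.data.frame(m, stringsAsFactors = FALSE)
  known <- match(labs, .starLabels)
  names(tab) <- ifelse(is.na(known), sub("^_", "", labs),
                       names(.starLabels)[known])
  for (cn in intersect(c("class", .metaNumeric), names(tab))) {
    tab[[cn]][tab[[cn]] == "NA"] <- NA
    tab[[cn]] <- as.numeric(tab[[cn]])
  }
  if ("class" %in% names(tab)) tab$class <- as.integer(tab$class)
  tab
}

writeStarLoop <- function(table, path) {
  cols <- intersect(names(.starLabels), names(table))
  extra <- setdiff(names(table), cols)
  labs <- c(.starLabels[cols], if (length(extra)) paste0("_", extra))
  header <- c("", "data_particles", "", "loop_",
              sprintf("%s #%d", labs, seq_along(labs)))
  body <- table[, c(cols, extra), drop = FALSE]
  for (cn in names(body)) {
    body[[cn]] <- if (is.numeric(body[[cn]]) && !is.integer(body[[cn]])) {
      format(body[[cn]], digits = 10, trim = TRUE, scientific = FALSE)
    } else as.character(body[[cn]])
  }
  rows <- do.call(paste, c(unname(as.list(body)), sep = "  "))
  writeLines(c(header, rows, ""), path)
}
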