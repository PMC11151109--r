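#' @include AllClasses.R AllGenerics.R utils.R io.R
NULL

#' Construct a CircleMark
#'
#' @param role \code{"distal_anchor"} (the large circle placed tangent to the
#'   curve of the distal end of the gonad) or \code{"nucleus"} (the smaller
#'   circle around the nucleus center).
#' @param center (x, y) pixel coordinates of the circle center.
#' @param radius radius in pixels, > 0.
#' @return a \linkS4class{CircleMark}.
#' @export
circleMark <- function(role, center, radius) {
  new("CircleMark", role = role, center = as.numeric(center),
      radius = as.numeric(radius))
}

#' X coordinate of the distal origin defined by the anchor circle
#'
#' The distal end of the gonad is designated as the intersection of the
#' gonad's distal end with the inner arc of the anchor circle. On the
#' straightened image (distal at left, axis horizontal) that inner-arc point
#' is the leftmost point of the circle, i.e. \code{center.x - radius}.
#'
#' @param anchor a \linkS4class{CircleMark} with role \code{distal_anchor}.
#' @return the origin's x pixel coordinate.
#' @examples
#' distalOriginX(circleMark("distal_anchor", c(100, 60), 40))  # 60
#' @export
distalOriginX <- function(anchor) {
  stopifnot(is(anchor, "CircleMark"))
  if (anchor@role != "distal_anchor")
    dtcStop("dtcError_wrongRole",
            "distal origin requires a circle with role 'distal_anchor', got '%s'",
            anchor@role)
  anchor@center[1] - anchor@radius
}

#' Signed distance of a mark from the distal origin, in micrometres
#'
#' Marks are logged by their distance along the X axis from the distal
#' origin: \code{(x - originX) * pixelSizeXY}. Positive distances are
#' proximal (rightward); the mark's y coordinate is recorded but excluded
#' from the distance by contract.
#'
#' @param x the mark's x pixel coordinate (vectorized).
#' @param originX origin x from \code{\link{distalOriginX}}.
#' @param pixelSizeXY micrometres per pixel, > 0.
#' @return signed distance(s) in micrometres.
#' @export
markDistanceUm <- function(x, originX, pixelSizeXY) {
  stopifnot(pixelSizeXY > 0)
  (x - originX) * pixelSizeXY
}

#' Assemble a MarkupRecord
#'
#' Derived values (per-mark distances, per-type counts) are computed here and
#' verified by the class validity: they are pure functions of the stored
#' marks.
#'
#' @param specimenId specimen token.
#' @param pixelSizeXY micrometres per pixel.
#' @param distalAnchor \linkS4class{CircleMark}, role \code{distal_anchor}.
#' @param marks data.frame with columns \code{feature_type, x, y}; may be
#'   empty.
#' @param nucleus optional \linkS4class{CircleMark}, role \code{nucleus}; its
#'   center is added to the marks as a \code{nucleus_center} feature.
#' @param vocabulary allowed feature types (default
#'   \code{\link{DEFAULT_VOCABULARY}}).
#' @return a \linkS4class{MarkupRecord}.
#' @export
markupRecord <- function(specimenId, pixelSizeXY, distalAnchor,
                         marks = data.frame(feature_type = character(),
                                            x = numeric(), y = numeric()),
                         nucleus = NULL,
                         vocabulary = DEFAULT_VOCABULARY) {
  marks <- as.data.frame(marks, stringsAsFactors = FALSE)
  if (!is.null(nucleus) && !("nucleus_center" %in% marks$feature_type))
    marks <- rbind(marks,
                   data.frame(feature_type = "nucleus_center",
                              x = nucleus@center[1], y = nucleus@center[2],
                              stringsAsFactors = FALSE))
  bad <- setdiff(unique(marks$feature_type), vocabulary)
  if (length(bad))
    dtcStop("dtcError_unknownFeature",
            "feature type(s) not in vocabulary: %s", paste(bad, collapse = ", "))
  ox <- distalOriginX(distalAnchor)
  dist <- markDistanceUm(marks$x, ox, pixelSizeXY)
  cnt <- table(factor(marks$feature_type, levels = vocabulary))
  new("MarkupRecord", specimenId = specimenId,
      pixelSizeXY = as.numeric(pixelSizeXY),
      distalAnchor = distalAnchor, nucleus = nucleus, marks = marks,
      vocabulary = vocabulary,
      distanceUm = as.numeric(dist),
      counts = stats::setNames(as.integer(cnt), vocabulary))
}

#' Build a MarkupRecord from an annotation file or list
#'
#' @param annotations path to an annotation JSON or a list from
#'   \code{\link{readAnnotations}}.
#' @param specimenId specimen token.
#' @param pixelSizeXY micrometres per pixel.
#' @param vocabulary allowed feature types.
#' @return a \linkS4class{MarkupRecord}.
#' @export
markupRecordFromAnnotations <- function(annotations, specimenId, pixelSizeXY,
                                        vocabulary = DEFAULT_VOCABULARY) {
  ann <- if (is.character(annotations)) readAnnotations(annotations)
         else annotations
  markupRecord(specimenId, pixelSizeXY, ann$distal_anchor,
               marks = ann$marks, nucleus = ann$nucleus,
               vocabulary = vocabulary)
}

#' Measure all markups of one specimen
#'
#' Emits the full per-specimen measurement table: one detail row per mark
#' (columns \code{specimen_id, feature_type, index, x_px, y_px,
#' distance_um}; \code{index} numbers marks within their type), a detail row
#' for the distal origin itself (distance 0), and one summary row per
#' vocabulary type whose count is carried in the \code{index} column with NA
#' coordinates. The anchor circle, optional nucleus circle (center and
#' radius, the radius also in micrometres) and pixel size are written as
#' \code{#}-prefixed header lines so the record round-trips through the
#' file.
#'
#' When \code{outDir} is given the table is written as tab-delimited text to
#' \code{\link{markupTablePath}(specimenId, outDir)} — a unique automatic
#' filename matching the specimen filename.
#'
#' @param record a \linkS4class{MarkupRecord} (must have a distal anchor).
#' @param outDir optional output directory for the TSV.
#' @return the table (data.frame) invisibly carrying the output path in
#'   attribute \code{"path"} when written.
#' @export
measureAllMarkups <- function(record, outDir = NULL) {
  stopifnot(is(record, "MarkupRecord"))
  ox <- distalOriginX(record@distalAnchor)
  m <- record@marks
  idx <- if (nrow(m))
    stats::ave(seq_len(nrow(m)), m$feature_type, FUN = seq_along)
  else integer()
  detail <- data.frame(
    specimen_id = rep(record@specimenId, nrow(m)),
    feature_type = m$feature_type,
    index = as.integer(idx),
    x_px = m$x, y_px = m$y,
    distance_um = record@distanceUm,
    stringsAsFactors = FALSE)
  origin <- data.frame(
    specimen_id = record@specimenId, feature_type = "distal_origin",
    index = 0L, x_px = ox, y_px = record@distalAnchor@center[2],
    distance_um = 0, stringsAsFactors = FALSE)
  summary <- data.frame(
    specimen_id = record@specimenId,
    feature_type = names(record@counts),
    index = as.integer(record@counts),
    x_px = NA_real_, y_px = NA_real_, distance_um = NA_real_,
    stringsAsFactors = FALSE)
  tab <- rbind(origin, detail, summary)
  rownames(tab) <- NULL
  if (!is.null(outDir)) {
    path <- markupTablePath(record@specimenId, outDir)
    writeMarkupTable(record, tab, path)
    attr(tab, "path") <- path
  }
  tab
}

writeMarkupTable <- function(record, tab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(
    sprintf("# specimen_id: %s", record@specimenId),
    sprintf("# pixel_size_um: %.10g", record@pixelSizeXY),
    sprintf("# distal_anchor: %.4f %.4f %.4f",
            record@distalAnchor@center[1], record@distalAnchor@center[2],
            record@distalAnchor@radius))
  if (!is.null(record@nucleus))
    hdr <- c(hdr, sprintf("# nucleus: %.4f %.4f %.4f",
                          record@nucleus@center[1], record@nucleus@center[2],
                          record@nucleus@radius),
             sprintf("# nucleus_radius_um: %.4f",
                     record@nucleus@radius * record@pixelSizeXY))
  hdr <- c(hdr, sprintf("# vocabulary: %s",
                        paste(record@vocabulary, collapse = " ")))
  writeLines(hdr, con)
  out <- tab
  for (col in c("x_px", "y_px", "distance_um"))
    out[[col]] <- ifelse(is.na(out[[col]]), "NA", sprintf("%.4f", out[[col]]))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a markup table back into a MarkupRecord
#'
#' Inverse of \code{\link{measureAllMarkups}}' TSV output: circles and pixel
#' size come from the \code{#} header lines, marks from the detail rows
#' (rows with coordinates, excluding the \code{distal_origin} row), and the
#' derived distances and counts are recomputed — by the MarkupRecord
#' invariant they must match what was written.
#'
#' @param path TSV written by \code{measureAllMarkups}.
#' @return a \linkS4class{MarkupRecord}.
#' @export
readMarkupTable <- function(path) {
  if (!file.exists(path))
    dtcStop("dtcError_missingFile", "markup table does not exist: %s", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  val <- function(key) sub(paste0("^# ", key, ": *"), "",
                           grep(paste0("^# ", key, ":"), hdr, value = TRUE))
  nums <- function(key) as.numeric(strsplit(val(key), " +")[[1]])
  anc <- nums("distal_anchor")
  nucLine <- grep("^# nucleus:", hdr, value = TRUE)
  nuc <- if (length(nucLine)) {
    v <- as.numeric(strsplit(sub("^# nucleus: *", "", nucLine), " +")[[1]])
    circleMark("nucleus", v[1:2], v[3])
  }
  vocab <- strsplit(val("vocabulary"), " +")[[1]]
  tab <- utils::read.delim(text = lines[!grepl("^#", lines)],
                           stringsAsFactors = FALSE)
  detail <- tab[!is.na(tab$x_px) & tab$feature_type != "distal_origin", ]
  marks <- data.frame(feature_type = detail$feature_type,
                      x = detail$x_px, y = detail$y_px,
                      stringsAsFactors = FALSE)
  markupRecord(val("specimen_id"), nums("pixel_size_um"),
               circleMark("distal_anchor", anc[1:2], anc[3]),
               marks = marks, nucleus = nuc, vocabulary = vocab)
}
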