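#' @include AllClasses.R AllGenerics.R utils.R
NULL

# --- calibration metadata -------------------------------------------------
#
# TIFFs written by this package carry their physical calibration in a JSON
# sidecar "<image>.meta.json" (pixel size, z step, bit depth, provenance).
# When reading, calibration precedence is: explicit override > TIFF
# resolution/description metadata > sidecar > error. A silent default um
# value would corrupt every downstream distance, so absence is an error.

metaPath <- function(path) paste0(path, ".meta.json")

writeMeta <- function(path, meta) {
  jsonlite::write_json(meta, metaPath(path), auto_unbox = TRUE, digits = NA,
                       null = "null")
}

readMeta <- function(path) {
  mp <- metaPath(path)
  if (!file.exists(mp)) return(NULL)
  jsonlite::read_json(mp, simplifyVector = TRUE)
}

# pixel size (um/px) from TIFF tags: resolution is stored as pixels per
# unit; ImageJ-style description lines can carry the z spacing
calibrationFromTags <- function(attrs) {
  out <- list(pixelSize = NULL, zStep = NULL)
  xres <- attrs[["x.resolution"]]
  unit <- attrs[["resolution.unit"]]
  if (!is.null(xres) && is.finite(xres) && xres > 0 && !is.null(unit)) {
    umPerUnit <- switch(unit, cm = 1e4, inch = 2.54e4, NULL)
    if (!is.null(umPerUnit)) out$pixelSize <- umPerUnit / xres
  }
  desc <- attrs[["description"]]
  if (!is.null(desc)) {
    m <- regmatches(desc, regexec("spacing=([0-9.eE+-]+)", desc))[[1]]
    if (length(m) == 2) out$zStep <- as.numeric(m[2])
  }
  out
}

#' Read a calibrated Z-stack from a multi-page grayscale TIFF
#'
#' Pages become Z planes in page order; the specimen id is the source
#' filename stem. Calibration is resolved with precedence explicit override >
#' TIFF metadata (resolution tags for pixel size, an ImageJ-style
#' \code{spacing=} description line for the z step) > JSON sidecar written by
#' \code{\link{writeImage}} > error, because a silently assumed micron value
#' would corrupt every downstream distance.
#'
#' @param path multi-page grayscale TIFF (8- or 16-bit).
#' @param pixelSize optional override, micrometres per pixel.
#' @param zStep optional override, micrometres between planes.
#' @return a \linkS4class{CalibratedStack}.
#' @examples
#' s <- generateDtcStack(synthParams(seed = 1))$stack
#' tf <- file.path(tempdir(), "demo.tif")
#' writeImage(s, tf)
#' s2 <- readStack(tf)
#' pixelSizeXY(s2)
#' @export
readStack <- function(path, pixelSize = NULL, zStep = NULL) {
  if (!file.exists(path))
    dtcStop("dtcError_missingFile", "input file does not exist: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) > 2L, logical(1))))
    dtcStop("dtcError_multiChannel",
            "multi-channel TIFF not supported: %s", path)
  attrs <- attributes(pages[[1]])
  bits <- attrs[["bits.per.sample"]]
  if (is.null(bits)) bits <- 16L
  tagCal <- calibrationFromTags(attrs)
  meta <- readMeta(path)
  px <- pixelSize %||% tagCal$pixelSize %||% meta$pixel_size_um
  zs <- zStep %||% tagCal$zStep %||% meta$z_step_um
  if (is.null(px) || is.null(zs))
    dtcStop("dtcError_missingCalibration",
            "no calibration for %s: supply pixelSize/zStep or a metadata sidecar",
            path)
  planes <- lapply(pages, function(p) {
    storage.mode(p) <- "integer"
    attributes(p) <- list(dim = dim(p))
    p
  })
  new("CalibratedStack",
      specimenId = sub("\\.[^.]*$", "", basename(path)),
      planes = planes, pixelSizeXY = as.numeric(px), zStep = as.numeric(zs),
      bitDepth = as.integer(bits))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn writeImage write a stack as a multi-page 16-bit TIFF plus a
#'   calibration sidecar.
#' @export
setMethod("writeImage", "CalibratedStack", function(x, path, ...) {
  checkWritable(path)
  denom <- 2^x@bitDepth - 1
  bits <- as.integer(x@bitDepth)
  tiff::writeTIFF(lapply(x@planes, function(p) p / denom), path,
                  bits.per.sample = bits)
  writeMeta(path, list(specimen_id = x@specimenId,
                       pixel_size_um = x@pixelSizeXY,
                       z_step_um = x@zStep,
                       bit_depth = x@bitDepth,
                       kind = "stack"))
  invisible(path)
})

#' @describeIn writeImage write a (possibly float-valued) projected or
#'   straightened image as 16-bit TIFF. Values are divided by
#'   \code{scaleMax} (default 65535) and quantized to 16 bits; the scale is
#'   recorded in the sidecar so the quantization contract is explicit.
#' @param scaleMax intensity mapped to the top of the 16-bit range.
#' @export
setMethod("writeImage", "ProjectedImage", function(x, path,
                                                   scaleMax = 65535, ...) {
  checkWritable(path)
  v <- pmin(x@pixels / scaleMax, 1)
  tiff::writeTIFF(round(v * 65535) / 65535, path, bits.per.sample = 16L)
  writeMeta(path, list(specimen_id = x@specimenId,
                       pixel_size_um = x@pixelSizeXY,
                       scale_max = scaleMax,
                       kind = "image",
                       provenance = x@provenance))
  invisible(path)
})

#' @describeIn writeImage write a binary mask as 8-bit 0/255 TIFF.
#' @export
setMethod("writeImage", "BinaryImage", function(x, path, ...) {
  checkWritable(path)
  tiff::writeTIFF(x@mask * 1.0, path, bits.per.sample = 8L)
  writeMeta(path, list(pixel_size_um = x@pixelSizeXY,
                       threshold_value = x@thresholdValue,
                       threshold_method = x@thresholdMethod,
                       kind = "mask"))
  invisible(path)
})

#' @describeIn writeImage write a raw numeric matrix; logical/0-1 matrices
#'   become 8-bit 0/255, anything else is treated as 16-bit intensities.
#' @export
setMethod("writeImage", "matrix", function(x, path, ...) {
  checkWritable(path)
  if (is.logical(x) || all(x %in% c(0, 1)))
    tiff::writeTIFF(x * 1.0, path, bits.per.sample = 8L)
  else
    tiff::writeTIFF(pmin(x / 65535, 1), path, bits.per.sample = 16L)
  invisible(path)
})

checkWritable <- function(path) {
  dir <- dirname(path)
  if (!dir.exists(dir))
    dtcStop("dtcError_unwritablePath",
            "parent directory does not exist: %s", dir)
}

#' Read back a projected image written by writeImage
#'
#' Restores the intensity scale and provenance from the calibration sidecar.
#'
#' @param path TIFF written by the ProjectedImage method of
#'   \code{\link{writeImage}}.
#' @return a \linkS4class{ProjectedImage}.
#' @export
readProjectedImage <- function(path) {
  if (!file.exists(path))
    dtcStop("dtcError_missingFile", "input file does not exist: %s", path)
  meta <- readMeta(path)
  if (is.null(meta))
    dtcStop("dtcError_missingCalibration",
            "no metadata sidecar next to %s", path)
  px <- tiff::readTIFF(path, as.is = TRUE)
  scaleMax <- meta$scale_max %||% 65535
  prov <- meta$provenance %||% list()
  if (is.data.frame(prov)) prov <- split(prov, seq_len(nrow(prov)))
  new("ProjectedImage", specimenId = meta$specimen_id %||% "image",
      pixels = px / 65535 * scaleMax,
      pixelSizeXY = as.numeric(meta$pixel_size_um),
      provenance = lapply(prov, as.list))
}

#' Deterministic markup-table path for a specimen
#'
#' Every specimen's measurement table gets a unique automatic filename that
#' matches the specimen filename: \code{<specimen_id>.markup.tsv}. Distinct
#' ids map to distinct paths; ids containing path separators are rejected.
#'
#' @param specimenId non-empty specimen token (no path separators).
#' @param dir directory the table lives in (default current directory).
#' @return the file path.
#' @examples
#' markupTablePath("worm01")
#' @export
markupTablePath <- function(specimenId, dir = ".") {
  if (!is.character(specimenId) || length(specimenId) != 1L ||
      !nzchar(specimenId))
    dtcStop("dtcError_badSpecimenId", "specimenId must be a non-empty string")
  if (grepl("[/\\\\]", specimenId))
    dtcStop("dtcError_badSpecimenId",
            "specimenId must not contain path separators: %s", specimenId)
  file.path(dir, paste0(specimenId, ".markup.tsv"))
}

#' Read an annotation JSON file
#'
#' The annotation interchange format is
#' \code{\{"distal_anchor": \{"center": [x, y], "radius": r\},
#' "nucleus": \{...\} | null,
#' "marks": [\{"type": "branchpoint", "pos": [x, y]\}, ...]\}}.
#'
#' @param path JSON file.
#' @return a list with elements \code{distal_anchor} (\linkS4class{CircleMark}),
#'   \code{nucleus} (\linkS4class{CircleMark} or NULL) and \code{marks}
#'   (data.frame feature_type, x, y).
#' @export
readAnnotations <- function(path) {
  if (!file.exists(path))
    dtcStop("dtcError_missingFile", "annotation file does not exist: %s", path)
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$distal_anchor))
    dtcStop("dtcError_missingAnchor", "annotations lack a distal_anchor: %s",
            path)
  circ <- function(role, node)
    new("CircleMark", role = role,
        center = as.numeric(unlist(node$center)),
        radius = as.numeric(node$radius))
  mk <- if (length(j$marks)) {
    data.frame(
      feature_type = vapply(j$marks, function(m) as.character(m$type), ""),
      x = vapply(j$marks, function(m) as.numeric(m$pos[[1]]), 0),
      y = vapply(j$marks, function(m) as.numeric(m$pos[[2]]), 0),
      stringsAsFactors = FALSE)
  } else {
    data.frame(feature_type = character(), x = numeric(), y = numeric(),
               stringsAsFactors = FALSE)
  }
  list(distal_anchor = circ("distal_anchor", j$distal_anchor),
       nucleus = if (!is.null(j$nucleus)) circ("nucleus", j$nucleus),
       marks = mk)
}

#' Write an annotation list to JSON
#'
#' Inverse of \code{\link{readAnnotations}}.
#'
#' @param ann list as returned by \code{readAnnotations} or
#'   \code{\link{renderAnnotations}}.
#' @param path destination JSON file.
#' @export
writeAnnotations <- function(ann, path) {
  asNode <- function(cm)
    if (is.null(cm)) NULL else
      list(center = as.numeric(cm@center), radius = as.numeric(cm@radius))
  mk <- ann$marks
  marksList <- if (nrow(mk)) lapply(seq_len(nrow(mk)), function(i)
    list(type = mk$feature_type[i], pos = c(mk$x[i], mk$y[i]))) else list()
  jsonlite::write_json(
    list(distal_anchor = asNode(ann$distal_anchor),
         nucleus = asNode(ann$nucleus),
         marks = marksList),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write a Sholl profile as CSV
#'
#' Columns are exactly \code{radius_um, intersections}; the center, step and
#' calibration are carried in \code{#}-prefixed header lines so the profile
#' round-trips exactly.
#'
#' @param profile a \linkS4class{ShollProfile}.
#' @param path destination CSV.
#' @export
writeShollProfile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# center_px: %.10g %.10g", profile@center[1], profile@center[2]),
    sprintf("# step_um: %.10g", profile@stepUm),
    sprintf("# pixel_size_um: %.10g", profile@pixelSizeXY),
    "radius_um,intersections"), con)
  if (length(profile@radiiUm))
    writeLines(sprintf("%.10g,%d", profile@radiiUm, profile@counts), con)
  invisible(path)
}

#' Read a Sholl profile CSV written by writeShollProfile
#'
#' @param path CSV file.
#' @return a \linkS4class{ShollProfile}.
#' @export
readShollProfile <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    as.numeric(strsplit(sub(paste0("^# ", key, ": *"), "", ln), " ")[[1]])
  }
  body <- lines[!grepl("^#", lines)]
  df <- if (length(body) > 1)
    utils::read.csv(text = body, stringsAsFactors = FALSE)
  else data.frame(radius_um = numeric(), intersections = integer())
  new("ShollProfile", center = getv("center_px"), stepUm = getv("step_um"),
      radiiUm = as.numeric(df$radius_um),
      counts = as.integer(df$intersections),
      pixelSizeXY = getv("pixel_size_um"))
}
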