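#' @include AllClasses.R AllGenerics.R utils.R io.R optimize.R straighten.R
#' @include markup.R sholl.R synth.R
NULL

knownConfigKeys <- list(
  top = c("inputs", "outDir", "stages", "pixelSize", "zStep",
          "optimize", "straighten", "markup", "sholl"),
  optimize = c("gamma", "backgroundFraction", "outputMax"),
  straighten = c("boxLengthPx", "boxHeightPx", "spacingPx"),
  markup = c("vocabulary"),
  sholl = c("stepUm", "maxRadiusUm", "threshold", "fixedValue", "center",
            "source")
)

#' Resolve and validate a pipeline configuration
#'
#' Fills defaults for every stage block and rejects unknown keys (a typoed
#' parameter must never be silently ignored). The resolved configuration is
#' written next to the outputs by \code{\link{runPipeline}} so that any
#' result file can be traced back to the exact parameters that produced it.
#'
#' @param config a list, or the path of a JSON config file. Recognized keys:
#'   \code{inputs} (character vector of stack TIFFs, or a glob pattern),
#'   \code{outDir}, \code{stages} (subset of optimize, straighten, markup,
#'   sholl), \code{pixelSize}/\code{zStep} calibration overrides, and the
#'   per-stage parameter blocks \code{optimize} (gamma, backgroundFraction,
#'   outputMax), \code{straighten} (boxLengthPx, boxHeightPx, spacingPx),
#'   \code{markup} (vocabulary), \code{sholl} (stepUm, maxRadiusUm,
#'   threshold, fixedValue, center, source). Per-specimen straightening
#'   paths and annotations are looked up next to each input as
#'   \code{<stem>.path.json} and \code{<stem>.ann.json}.
#' @return the resolved config list.
#' @export
resolveConfig <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  bad <- setdiff(names(config), knownConfigKeys$top)
  if (length(bad))
    dtcStop("dtcError_unknownConfigKey",
            "unknown config key(s): %s", paste(bad, collapse = ", "))
  for (blk in c("optimize", "straighten", "markup", "sholl")) {
    bad <- setdiff(names(config[[blk]]), knownConfigKeys[[blk]])
    if (length(bad))
      dtcStop("dtcError_unknownConfigKey",
              "unknown key(s) in '%s' block: %s", blk,
              paste(bad, collapse = ", "))
  }
  def <- function(block, key, value)
    if (is.null(config[[block]][[key]])) value else config[[block]][[key]]
  config$stages <- config$stages %||% c("optimize", "straighten", "sholl")
  config$optimize <- list(
    gamma = def("optimize", "gamma", 0.5),
    backgroundFraction = def("optimize", "backgroundFraction", 0.001),
    outputMax = def("optimize", "outputMax", 65535))
  config$straighten <- list(
    boxLengthPx = def("straighten", "boxLengthPx", 550L),
    boxHeightPx = def("straighten", "boxHeightPx", 120L),
    spacingPx = def("straighten", "spacingPx", 1))
  config$markup <- list(
    vocabulary = def("markup", "vocabulary", DEFAULT_VOCABULARY))
  config$sholl <- list(
    stepUm = def("sholl", "stepUm", 1.0),
    maxRadiusUm = def("sholl", "maxRadiusUm", NULL),
    threshold = def("sholl", "threshold", "otsu"),
    fixedValue = def("sholl", "fixedValue", NULL),
    center = def("sholl", "center", NULL),
    source = def("sholl", "source", "straightened"))
  if (length(config$inputs) == 1L && grepl("[*?]", config$inputs))
    config$inputs <- Sys.glob(config$inputs)
  config
}

#' Run the full pipeline over a batch of specimens
#'
#' Executes the requested stages in order — optimize (maximum projection,
#' background subtraction, gamma), straighten (curve-guided resampling and
#' fixed-box crop), markup (measurement table), sholl (binarize and profile)
#' — for every input stack, keyed throughout by the input filename stem as
#' the specimen id so samples and data can never be mismatched in large
#' batches. Per-specimen failures abort that specimen, the batch continues,
#' and failures are summarized in the returned status.
#'
#' Every file written is listed in \code{manifest.json} with its MD5 content
#' hash, and the resolved configuration is written next to the outputs
#' (\code{config.resolved.json}); together they re-derive which config
#' produced which file. Re-running with identical config and inputs is
#' byte-reproducible.
#'
#' @param config list or JSON path, see \code{\link{resolveConfig}}.
#' @return (invisibly) a list: \code{status} (0 if all specimens succeeded),
#'   \code{manifest} (data.frame specimen, stage, file, md5),
#'   \code{failures} (named character of error messages).
#' @export
runPipeline <- function(config) {
  cfg <- resolveConfig(config)
  if (is.null(cfg$outDir)) dtcStop("dtcError_badConfig", "config needs outDir")
  if (!length(cfg$inputs))
    dtcStop("dtcError_badConfig", "config needs at least one input")
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(cfg, file.path(cfg$outDir, "config.resolved.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  manifest <- data.frame(specimen = character(), stage = character(),
                         file = character(), md5 = character(),
                         stringsAsFactors = FALSE)
  failures <- character()
  addFile <- function(specimen, stage, file) {
    manifest <<- rbind(manifest, data.frame(
      specimen = specimen, stage = stage, file = basename(file),
      md5 = unname(tools::md5sum(file)), stringsAsFactors = FALSE))
    sidecar <- metaPath(file)
    if (file.exists(sidecar))
      manifest <<- rbind(manifest, data.frame(
        specimen = specimen, stage = stage, file = basename(sidecar),
        md5 = unname(tools::md5sum(sidecar)), stringsAsFactors = FALSE))
  }

  for (input in cfg$inputs) {
    stem <- sub("\\.[^.]*$", "", basename(input))
    res <- tryCatch({
      stack <- readStack(input, pixelSize = cfg$pixelSize, zStep = cfg$zStep)
      current <- NULL
      if ("optimize" %in% cfg$stages) {
        current <- optimizeImage(stack,
                                 gamma = cfg$optimize$gamma,
                                 backgroundFraction =
                                   cfg$optimize$backgroundFraction,
                                 outputMax = cfg$optimize$outputMax)
        f <- file.path(cfg$outDir, paste0(stem, ".opt.tif"))
        writeImage(current, f, scaleMax = cfg$optimize$outputMax)
        addFile(stem, "optimize", f)
      } else current <- maxProject(stack)
      straightened <- NULL
      if ("straighten" %in% cfg$stages) {
        pf <- file.path(dirname(input), paste0(stem, ".path.json"))
        cp <- readCurvePath(pf)
        band <- straightenImage(current, cp, spacingPx =
                                  cfg$straighten$spacingPx)
        straightened <- cropFixedBox(band,
                                     boxLengthPx = cfg$straighten$boxLengthPx,
                                     boxHeightPx = cfg$straighten$boxHeightPx,
                                     specimenId = stem,
                                     pixelSizeXY = current@pixelSizeXY)
        f <- file.path(cfg$outDir, paste0(stem, ".straight.tif"))
        writeImage(straightened, f, scaleMax = cfg$optimize$outputMax)
        addFile(stem, "straighten", f)
      }
      if ("markup" %in% cfg$stages) {
        af <- file.path(dirname(input), paste0(stem, ".ann.json"))
        rec <- markupRecordFromAnnotations(af, stem, stack@pixelSizeXY,
                                           vocabulary =
                                             cfg$markup$vocabulary)
        tab <- measureAllMarkups(rec, outDir = cfg$outDir)
        addFile(stem, "markup", attr(tab, "path"))
      }
      if ("sholl" %in% cfg$stages) {
        src <- if (!is.null(straightened) &&
                   cfg$sholl$source == "straightened") straightened
               else current
        bin <- binarize(src, method = cfg$sholl$threshold,
                        fixedValue = cfg$sholl$fixedValue)
        f <- file.path(cfg$outDir, paste0(stem, ".mask.tif"))
        writeImage(bin, f)
        addFile(stem, "sholl", f)
        if (is.null(cfg$sholl$center))
          dtcStop("dtcError_badConfig",
                  "sholl stage requires a user-defined center in the config")
        prof <- shollProfile(bin, center = as.numeric(cfg$sholl$center),
                             stepUm = cfg$sholl$stepUm,
                             maxRadiusUm = cfg$sholl$maxRadiusUm)
        f <- file.path(cfg$outDir, paste0(stem, ".sholl.csv"))
        writeShollProfile(prof, f)
        addFile(stem, "sholl", f)
      }
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) failures[stem] <- res
  }
  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       digits = NA, pretty = TRUE)
  out <- list(status = if (length(failures)) 1L else 0L,
              manifest = manifest, failures = failures)
  invisible(out)
}
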