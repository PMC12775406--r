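#' Write and read ion-count stacks as multi-page TIFF
#'
#' One 16-bit multi-page TIFF per ion species (page = plane) plus a YAML
#' sidecar recording species, geometry and instrument mode. Counts must be
#' below 2^16 per pixel and plane.
#'
#' @param stack An [IonCountStack-class].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the sidecar path.
#' @export
writeIonStack <- function(stack, dir, prefix = "stack") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  for (sp in ionSpecies(stack)) {
    a <- ionCounts(stack, sp)
    if (max(a) >= 65536)
      stop("counts exceed 16-bit range; cannot serialize")
    pages <- lapply(seq_len(dim(a)[1]), function(p)
      a[p, , ] / 65535)
    f <- file.path(dir, paste0(prefix, "_", sp, ".tif"))
    tiff::writeTIFF(pages, f, bits.per.sample = 16)
    files[[sp]] <- basename(f)
  }
  meta <- list(species = files,
               pixel_size_um = pixelSizeUm(stack),
               instrument = instrumentMode(stack))
  meta_path <- file.path(dir, paste0(prefix, ".yaml"))
  yaml::write_yaml(meta, meta_path)
  invisible(meta_path)
}

#' @rdname writeIonStack
#' @param meta_path Path to the YAML sidecar written by [writeIonStack()].
#' @export
readIonStack <- function(meta_path) {
  meta <- yaml::read_yaml(meta_path)
  dir <- dirname(meta_path)
  counts <- list()
  for (sp in names(meta$species)) {
    pages <- tiff::readTIFF(file.path(dir, meta$species[[sp]]), all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    a <- array(0L, dim = c(length(pages), nrow(pages[[1]]),
                           ncol(pages[[1]])))
    for (p in seq_along(pages))
      a[p, , ] <- as.integer(round(pages[[p]] * 65535))
    counts[[sp]] <- a
  }
  IonCountStack(counts = counts, pixelSizeUm = meta$pixel_size_um,
                instrument = meta$instrument)
}

#' Write and read an ROISet (label-mask TIFF + annotation CSV)
#'
#' The mask is stored as a 16-bit label TIFF, the annotation table as CSV.
#'
#' @param rois An [ROISet-class].
#' @param mask_path Output path for the mask TIFF.
#' @param info_path Output path for the annotation CSV.
#' @return Invisibly, \code{info_path}.
#' @export
writeRoiSet <- function(rois, mask_path, info_path) {
  mask <- roiMask(rois)
  if (max(mask) >= 65536) stop("more than 2^16 labels; cannot serialize")
  tiff::writeTIFF(mask / 65535, mask_path, bits.per.sample = 16)
  utils::write.csv(roiInfo(rois), info_path, row.names = FALSE)
  invisible(info_path)
}

#' @rdname writeRoiSet
#' @export
readRoiSet <- function(mask_path, info_path) {
  m <- tiff::readTIFF(mask_path)
  mask <- matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
  info <- utils::read.csv(info_path, stringsAsFactors = FALSE)
  ROISet(mask = mask, info = info)
}

# recursively turn configuration values into yaml-preserving structures:
# data.frames become column maps tagged ".df", named vectors become maps
.yamlify <- function(x) {
  if (is.data.frame(x))
    return(c(list(.df = TRUE), lapply(as.list(x), unname)))
  if (is.list(x)) return(lapply(x, .yamlify))
  if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
  x
}

.unyamlify <- function(x) {
  if (!is.list(x)) return(x)
  if (isTRUE(x$.df)) {
    x$.df <- NULL
    return(as.data.frame(lapply(x, unlist), stringsAsFactors = FALSE))
  }
  scalars <- vapply(x, function(e) is.atomic(e) && length(e) == 1L, TRUE)
  if (length(x) && all(scalars) && !is.null(names(x)) &&
      all(vapply(x, is.numeric, TRUE)))
    return(unlist(x))
  lapply(x, .unyamlify)
}

#' Save and load simulation configurations as YAML
#'
#' Table-valued fields (enrichment tables, contents, rate tables) are
#' stored column-wise, named vectors as maps; both are reconstructed on
#' load.
#'
#' @param cfg A \code{PopulationConfig}, \code{SimSIMSConfig} or
#'   \code{BudgetParams}.
#' @param path YAML file path.
#' @return \code{loadConfig} returns the reconstructed object.
#' @export
saveConfig <- function(cfg, path) {
  x <- lapply(unclass(cfg), .yamlify)
  x$.class <- class(cfg)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname saveConfig
#' @export
loadConfig <- function(path) {
  x <- yaml::read_yaml(path)
  cls <- x$.class; x$.class <- NULL
  structure(lapply(x, .unyamlify), class = cls)
}
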