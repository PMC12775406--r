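#' @import methods
NULL

#' Closed vocabulary of ROI categories
#'
#' Cell and particle categories used throughout the package. Host cells are
#' split into type I (akinetes/heterocytes that are mutually adjacent, i.e.
#' sit at an akinete-heterocyte junction) and type II (enclosed by vegetative
#' cells), matching how cells are differentiated during single-cell isotope
#' analysis.
#'
#' @return Character vector of valid category labels.
#' @export
roiCategories <- function() {
  c("vegetative", "heterocyte_I", "heterocyte_II",
    "akinete_I", "akinete_II", "sporangium", "bacterium", "control")
}

#' @rdname roiCategories
#' @export
sporangialStages <- function() c("encysted", "mature", "collapsed", "none")

.HOST_CATEGORIES <- c("vegetative", "heterocyte_I", "heterocyte_II",
                      "akinete_I", "akinete_II")

#' IonCountStack: multi-plane ion-count images for one analysis raster
#'
#' Container for per-ion-species count images acquired over repeated planes
#' of a SIMS raster. Each species holds an integer array with dimensions
#' plane x row x col; all species share one geometry. Supported instrument
#' modes are \code{"large_geometry"} (CN- secondary ions: 12C14N, 13C14N,
#' 12C15N) and \code{"nano"} (C2-/CN- ions: 12C12C, 12C13C, 14N12C, 15N12C).
#'
#' @slot counts Named list of integer arrays (plane x row x col), one per
#'   ion species.
#' @slot pixelSizeUm Physical pixel size in micrometres.
#' @slot instrument Instrument mode, \code{"large_geometry"} or \code{"nano"}.
#'
#' @seealso [simulateIonStack()], [extractRoiCounts()]
#' @export
setClass("IonCountStack",
  representation(counts = "list", pixelSizeUm = "numeric",
                 instrument = "character"))

setValidity("IonCountStack", function(object) {
  msg <- character()
  if (length(object@counts) == 0L || is.null(names(object@counts)))
    msg <- c(msg, "counts must be a named, non-empty list of arrays")
  dims <- lapply(object@counts, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    msg <- c(msg, "each species array must be plane x row x col")
  if (length(unique(dims)) > 1L)
    msg <- c(msg, "all species must share identical array dimensions")
  if (length(msg) == 0L && dims[[1]][1] < 1L)
    msg <- c(msg, "at least one plane is required")
  for (sp in names(object@counts)) {
    x <- object@counts[[sp]]
    if (any(x < 0) || any(x != round(x)))
      msg <- c(msg, sprintf("counts for %s must be non-negative integers", sp))
  }
  if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be a single positive number")
  if (!object@instrument %in% c("large_geometry", "nano"))
    msg <- c(msg, "instrument must be 'large_geometry' or 'nano'")
  if (length(msg)) msg else TRUE
})

#' Construct an IonCountStack
#'
#' @param counts Named list of integer arrays (plane x row x col).
#' @param pixelSizeUm Pixel size in micrometres.
#' @param instrument \code{"large_geometry"} or \code{"nano"}.
#' @return An [IonCountStack-class] object.
#' @export
IonCountStack <- function(counts, pixelSizeUm, instrument = "large_geometry") {
  new("IonCountStack", counts = counts, pixelSizeUm = pixelSizeUm,
      instrument = instrument)
}

#' ROISet: label mask plus per-ROI annotations
#'
#' Pairs an integer label image (0 = background, k = ROI k) with an
#' annotation table describing each region of interest: its category,
#' sporangial development stage, link to the host cell(s) it parasitizes or
#' colonizes, filament membership, centroid, and distance to the nearest
#' host cell (used to split bacteria into associated and free-living).
#'
#' @slot mask Integer matrix; 0 is background, positive values are ROI ids.
#' @slot info data.frame with one row per ROI. Required columns:
#'   \code{roi_id}, \code{category}, \code{sporangial_stage},
#'   \code{host_link} (";"-separated roi ids or NA), \code{filament_id},
#'   \code{centroid_x_um}, \code{centroid_y_um},
#'   \code{min_distance_to_host_cell_um}, \code{infection_status}.
#'
#' @seealso [simulatePopulation()], [classifyFreeLiving()]
#' @export
setClass("ROISet", representation(mask = "matrix", info = "data.frame"))

.roi_info_cols <- c("roi_id", "category", "sporangial_stage", "host_link",
                    "filament_id", "centroid_x_um", "centroid_y_um",
                    "min_distance_to_host_cell_um", "infection_status")

setValidity("ROISet", function(object) {
  msg <- character()
  info <- object@info
  missing_cols <- setdiff(.roi_info_cols, names(info))
  if (length(missing_cols))
    msg <- c(msg, paste("info lacks columns:", paste(missing_cols, collapse = ", ")))
  if (length(msg)) return(msg)
  if (anyDuplicated(info$roi_id))
    msg <- c(msg, "roi_id values must be unique")
  bad_cat <- setdiff(unique(info$category), roiCategories())
  if (length(bad_cat))
    msg <- c(msg, paste("unknown categories:", paste(bad_cat, collapse = ", ")))
  bad_stage <- setdiff(unique(info$sporangial_stage), sporangialStages())
  if (length(bad_stage))
    msg <- c(msg, paste("unknown sporangial stages:", paste(bad_stage, collapse = ", ")))
  if (any(object@mask < 0) || any(object@mask != round(object@mask)))
    msg <- c(msg, "mask must contain non-negative integer labels")
  in_mask <- unique(as.integer(object@mask))
  orphan <- setdiff(setdiff(in_mask, 0L), info$roi_id)
  if (length(orphan))
    msg <- c(msg, paste("mask labels without annotation:", paste(orphan, collapse = ", ")))
  sp <- info[info$category == "sporangium", , drop = FALSE]
  if (nrow(sp) && (anyNA(sp$host_link) || any(!nzchar(sp$host_link))))
    msg <- c(msg, "every sporangium must carry a host_link")
  if (length(msg)) msg else TRUE
})

.parse_host_link <- function(x) {
  if (is.na(x) || !nzchar(x)) return(integer())
  as.integer(strsplit(as.character(x), ";", fixed = TRUE)[[1]])
}

#' Construct an ROISet
#'
#' @param mask Integer label matrix (0 = background).
#' @param info Annotation data.frame; see [ROISet-class].
#' @return An [ROISet-class] object.
#' @export
ROISet <- function(mask, info) {
  info$category <- as.character(info$category)
  info$sporangial_stage <- as.character(info$sporangial_stage)
  info$host_link <- as.character(info$host_link)
  new("ROISet", mask = mask, info = info)
}
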