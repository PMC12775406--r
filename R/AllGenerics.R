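#' Accessors for IonCountStack and ROISet
#'
#' @param object An [IonCountStack-class] or [ROISet-class].
#' @param species Ion-species label, e.g. \code{"12C14N"}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("ionSpecies", function(object) standardGeneric("ionSpecies"))

#' @rdname accessors
#' @export
setGeneric("ionCounts", function(object, species) standardGeneric("ionCounts"))

#' @rdname accessors
#' @export
setGeneric("nPlanes", function(object) standardGeneric("nPlanes"))

#' @rdname accessors
#' @export
setGeneric("pixelSizeUm", function(object) standardGeneric("pixelSizeUm"))

#' @rdname accessors
#' @export
setGeneric("instrumentMode", function(object) standardGeneric("instrumentMode"))

#' @rdname accessors
#' @export
setGeneric("roiMask", function(object) standardGeneric("roiMask"))

#' @rdname accessors
#' @export
setGeneric("roiInfo", function(object) standardGeneric("roiInfo"))

#' @rdname accessors
#' @export
setMethod("ionSpecies", "IonCountStack", function(object) names(object@counts))

#' @rdname accessors
#' @export
setMethod("ionCounts", "IonCountStack", function(object, species) {
  if (!species %in% names(object@counts))
    stop("unknown ion species: ", species)
  object@counts[[species]]
})

#' @rdname accessors
#' @export
setMethod("nPlanes", "IonCountStack", function(object) dim(object@counts[[1]])[1])

#' @rdname accessors
#' @export
setMethod("pixelSizeUm", "IonCountStack", function(object) object@pixelSizeUm)

#' @rdname accessors
#' @export
setMethod("instrumentMode", "IonCountStack", function(object) object@instrument)

#' @rdname accessors
#' @export
setMethod("roiMask", "ROISet", function(object) object@mask)

#' @rdname accessors
#' @export
setMethod("roiInfo", "ROISet", function(object) object@info)

setMethod("show", "IonCountStack", function(object) {
  d <- dim(object@counts[[1]])
  cat("IonCountStack (", object@instrument, ")\n", sep = "")
  cat("  species:", paste(names(object@counts), collapse = ", "), "\n")
  cat("  planes x rows x cols:", paste(d, collapse = " x "), "\n")
  cat("  pixel size:", object@pixelSizeUm, "um\n")
})

setMethod("show", "ROISet", function(object) {
  cat("ROISet with", nrow(object@info), "ROIs on a",
      paste(dim(object@mask), collapse = " x "), "mask\n")
  tab <- table(object@info$category)
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
})
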