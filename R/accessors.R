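#' Accessors for pdquant classes
#'
#' Slot access for [TissueImage-class], [WallGraph-class],
#' [GroundTruth-class] and [TimingSample-class] objects. Tables are returned
#' as plain data.frames.
#'
#' @param x a pdquant object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wallChannel", function(x) standardGeneric("wallChannel"))
#' @rdname accessors
#' @export
setMethod("wallChannel", "TissueImage", function(x) x@wallChannel)

#' @rdname accessors
#' @export
setGeneric("punctaChannel", function(x) standardGeneric("punctaChannel"))
#' @rdname accessors
#' @export
setMethod("punctaChannel", "TissueImage", function(x) x@punctaChannel)

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setMethod("pixelSize", "TissueImage", function(x) x@pixelSize)
#' @rdname accessors
#' @export
setMethod("pixelSize", "WallGraph", function(x) x@pixelSize)
#' @rdname accessors
#' @export
setMethod("pixelSize", "GroundTruth", function(x) x@pixelSize)

#' @rdname accessors
#' @export
setGeneric("cells", function(x) standardGeneric("cells"))
#' @rdname accessors
#' @export
setMethod("cells", "WallGraph", function(x) x@cells)
#' @rdname accessors
#' @export
setMethod("cells", "GroundTruth", function(x) x@cells)

#' @rdname accessors
#' @export
setGeneric("walls", function(x) standardGeneric("walls"))
#' @rdname accessors
#' @export
setMethod("walls", "WallGraph", function(x) x@walls)
#' @rdname accessors
#' @export
setMethod("walls", "GroundTruth", function(x) x@walls)

#' @rdname accessors
#' @export
setGeneric("junctions", function(x) standardGeneric("junctions"))
#' @rdname accessors
#' @export
setMethod("junctions", "WallGraph", function(x) x@junctions)
#' @rdname accessors
#' @export
setMethod("junctions", "GroundTruth", function(x) x@junctions)

#' @rdname accessors
#' @export
setGeneric("puncta", function(x) standardGeneric("puncta"))
#' @rdname accessors
#' @export
setMethod("puncta", "WallGraph", function(x) x@puncta)
#' @rdname accessors
#' @export
setMethod("puncta", "GroundTruth", function(x) x@puncta)

#' @rdname accessors
#' @export
setGeneric("wallPaths", function(x) standardGeneric("wallPaths"))
#' @rdname accessors
#' @export
setMethod("wallPaths", "WallGraph", function(x) x@wallPaths)

#' @rdname accessors
#' @export
setGeneric("cellLabels", function(x) standardGeneric("cellLabels"))
#' @rdname accessors
#' @export
setMethod("cellLabels", "WallGraph", function(x) x@cellLabels)

#' @rdname accessors
#' @export
setGeneric("skeletonMask", function(x) standardGeneric("skeletonMask"))
#' @rdname accessors
#' @export
setMethod("skeletonMask", "WallSkeleton", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("skeletonMask", "WallGraph", function(x) x@skeleton)

#' @rdname accessors
#' @export
setGeneric("degreeMap", function(x) standardGeneric("degreeMap"))
#' @rdname accessors
#' @export
setMethod("degreeMap", "WallSkeleton", function(x) x@degree)

#' @rdname accessors
#' @export
setGeneric("budBreakDays", function(x) standardGeneric("budBreakDays"))
#' @rdname accessors
#' @export
setMethod("budBreakDays", "TimingSample", function(x) x@days)

#' @rdname accessors
#' @export
setGeneric("nTotal", function(x) standardGeneric("nTotal"))
#' @rdname accessors
#' @export
setMethod("nTotal", "TimingSample", function(x) x@nTotal)

#' @rdname accessors
#' @export
setGeneric("sampleLabel", function(x) standardGeneric("sampleLabel"))
#' @rdname accessors
#' @export
setMethod("sampleLabel", "TimingSample", function(x) x@label)
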