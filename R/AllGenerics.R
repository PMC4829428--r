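#' @rdname FeatureIndex-class
#' @param x,object A `FeatureIndex`.
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname FeatureIndex-class
#' @export
setGeneric("featureKinds", function(x) standardGeneric("featureKinds"))

#' @rdname FeatureIndex-class
#' @export
setGeneric("featureRanges", function(x) standardGeneric("featureRanges"))

#' @rdname FeatureIndex-class
#' @export
setGeneric("nGeneLoci", function(x) standardGeneric("nGeneLoci"))

#' @rdname FeatureIndex-class
#' @export
setGeneric("nRepeatFamilies", function(x) standardGeneric("nRepeatFamilies"))

#' @rdname MztCounts
#' @param x An `MztCounts` object.
#' @export
setGeneric("sampleConditions", function(x) standardGeneric("sampleConditions"))

#' Evaluate a dispersion-mean trend
#'
#' @param object A [DispersionTrend-class].
#' @param mu Numeric vector of (positive) normalized means.
#' @return `a0 + a1 / mu`, the trend dispersion at each mean.
#' @examples
#' tr <- new("DispersionTrend", a0 = 0.05, a1 = 2)
#' trendDispersion(tr, c(10, 100, 1000))
#' @export
setGeneric("trendDispersion",
    function(object, mu) standardGeneric("trendDispersion"))
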