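#' @import methods
NULL

#' @export
setGeneric("frameIndex", function(x, ...) standardGeneric("frameIndex"))

#' @export
setGeneric("boxes", function(x, ...) standardGeneric("boxes"))

#' @export
setGeneric("tracks", function(x, ...) standardGeneric("tracks"))

#' @export
setGeneric("tracks<-", function(x, value) standardGeneric("tracks<-"))

#' @export
setGeneric("identities", function(x, ...) standardGeneric("identities"))

#' @export
setGeneric("featureMatrix", function(x, ...) standardGeneric("featureMatrix"))

#' @export
setGeneric("hasFeatures", function(x) standardGeneric("hasFeatures"))

#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @export
setGeneric("nDetections", function(x) standardGeneric("nDetections"))

#' Fit a classifier on labelled features and return resubstitution labels
#'
#' The contract behind classifier-based clustering: train on `X` with `labels`,
#' then predict labels for the same rows of `X`. Implementations must accept
#' classes with a single member.
#'
#' @param classifier a classifier specification object.
#' @param X numeric matrix, one row per observation.
#' @param labels integer vector of class labels, one per row of `X`.
#' @return integer vector of predicted labels, same length as `labels`,
#'   drawn from the label universe of `labels`.
#' @export
setGeneric("fitPredict", function(classifier, X, labels)
  standardGeneric("fitPredict"))
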