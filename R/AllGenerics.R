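#' @export
setGeneric("rhoBnb", function(object) standardGeneric("rhoBnb"))

#' @export
setGeneric("rhoBzinb", function(object) standardGeneric("rhoBzinb"))

#' @export
setGeneric("rhoNaiveBzinb", function(object) standardGeneric("rhoNaiveBzinb"))

#' @export
setGeneric("bzinbMoments", function(object) standardGeneric("bzinbMoments"))

#' @export
setGeneric("alpha0", function(object) standardGeneric("alpha0"))
#' @export
setGeneric("alpha1", function(object) standardGeneric("alpha1"))
#' @export
setGeneric("alpha2", function(object) standardGeneric("alpha2"))
#' @export
setGeneric("beta1", function(object) standardGeneric("beta1"))
#' @export
setGeneric("beta2", function(object) standardGeneric("beta2"))
#' @export
setGeneric("zeroInflation", function(object) standardGeneric("zeroInflation"))
#' @export
setGeneric("bnbParams", function(object) standardGeneric("bnbParams"))

#' @export
setGeneric("corrValues", function(object) standardGeneric("corrValues"))
#' @export
setGeneric("corrMethod", function(object) standardGeneric("corrMethod"))
#' @export
setGeneric("fitStatus", function(object) standardGeneric("fitStatus"))

#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))

#' @export
setGeneric("edges", function(object) standardGeneric("edges"))
#' @export
setGeneric("nodes", function(object) standardGeneric("nodes"))
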