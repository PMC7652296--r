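#' @rdname GenotypeMatrix-class
#' @param x,object a `GenotypeMatrix`
#' @export
setGeneric("nInd", function(x) standardGeneric("nInd"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("lociNames", function(x) standardGeneric("lociNames"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("indNames", function(x) standardGeneric("indNames"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("popNames", function(x) standardGeneric("popNames"))

#' @rdname LabeledMatrix-class
#' @param x a `LabeledMatrix`
#' @export
setGeneric("statName", function(x) standardGeneric("statName"))

#' @rdname LabeledMatrix-class
#' @export
setGeneric("pvalues", function(x) standardGeneric("pvalues"))

#' @rdname GridSpec-class
#' @param x a `GridSpec` (or object carrying one)
#' @export
setGeneric("seaMask", function(x) standardGeneric("seaMask"))

#' @rdname GridSpec-class
#' @export
setGeneric("cellCenters", function(x) standardGeneric("cellCenters"))

#' @rdname GridSpec-class
#' @export
setGeneric("cellAreasKm2", function(x) standardGeneric("cellAreasKm2"))
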