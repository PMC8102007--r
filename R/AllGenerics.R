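#' @rdname CellSet-class
#' @param object,x a package object.
#' @export
setGeneric("cells", function(object) standardGeneric("cells"))

#' @rdname CellSet-class
#' @export
setGeneric("nCells", function(object) standardGeneric("nCells"))

#' @rdname BackcrossFamily-class
#' @export
setGeneric("markers", function(object) standardGeneric("markers"))

#' Genotype matrix of one transmitting parent
#'
#' @param object a [BackcrossFamily-class].
#' @param origin `"hybrid"` or `"pure"`.
#' @return integer matrix, individuals x markers, coded 0/1/NA.
#' @export
setGeneric("genotypes", function(object, origin = "hybrid")
  standardGeneric("genotypes"))

#' @rdname BackcrossFamily-class
#' @export
setGeneric("phenotypes", function(object) standardGeneric("phenotypes"))

#' @rdname QTLScanResult-class
#' @export
setGeneric("scanTable", function(object) standardGeneric("scanTable"))

#' @rdname QTLScanResult-class
#' @export
setGeneric("peaks", function(object) standardGeneric("peaks"))

#' @rdname QTLScanResult-class
#' @export
setGeneric("lodThreshold", function(object) standardGeneric("lodThreshold"))
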