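#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
NULL

#' Accessor generics
#'
#' Accessors for the central S4 containers: \code{genomeID} returns the
#' genome identifier, \code{contigs} the nucleotide contigs as a
#' \code{DNAStringSet}, \code{genes} the gene models as a \code{GRanges},
#' \code{proteins} the protein sequences as an \code{AAStringSet},
#' \code{puls} the PUL call table, and \code{ruleTable} the substrate rule
#' table.
#'
#' @param x an object of the appropriate class.
#' @return The slot content (see class documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genomeID", function(x) standardGeneric("genomeID"))

#' @rdname accessors
#' @export
setGeneric("contigs", function(x) standardGeneric("contigs"))

#' @rdname accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @rdname accessors
#' @export
setGeneric("proteins", function(x) standardGeneric("proteins"))

#' @rdname accessors
#' @export
setGeneric("puls", function(x) standardGeneric("puls"))

#' @rdname accessors
#' @export
setGeneric("ruleTable", function(x) standardGeneric("ruleTable"))

#' @rdname accessors
#' @export
setGeneric("gcValues", function(x) standardGeneric("gcValues"))
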