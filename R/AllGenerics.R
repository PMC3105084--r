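#' @include AllClasses.R
NULL

#' Accessors for plastomeR classes
#'
#' Small generic accessors so downstream code never touches slots directly.
#'
#' @param x an object
#' @return the corresponding component
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))
#' @rdname accessors
#' @export
setGeneric("genomeTaxon", function(x) standardGeneric("genomeTaxon"))
#' @rdname accessors
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))
#' @rdname accessors
#' @export
setGeneric("genomeFeatures", function(x) standardGeneric("genomeFeatures"))
#' @rdname accessors
#' @export
setGeneric("regionLengths", function(x) standardGeneric("regionLengths"))
#' @rdname accessors
#' @export
setGeneric("junctions", function(x) standardGeneric("junctions"))
#' @rdname accessors
#' @export
setGeneric("motifs", function(x) standardGeneric("motifs"))
#' @rdname accessors
#' @export
setGeneric("characterStates", function(x) standardGeneric("characterStates"))
#' @rdname accessors
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))
#' @rdname accessors
#' @export
setGeneric("distances", function(x) standardGeneric("distances"))
#' @rdname accessors
#' @export
setGeneric("truthLog", function(x) standardGeneric("truthLog"))
#' @rdname accessors
#' @export
setGeneric("trueAlignment", function(x) standardGeneric("trueAlignment"))
#' @rdname accessors
#' @export
setGeneric("leafRecords", function(x) standardGeneric("leafRecords"))

#' @rdname accessors
setMethod("genomeId", "GenomeRecord", function(x) x@id)
#' @rdname accessors
setMethod("genomeTaxon", "GenomeRecord", function(x) x@taxon)
#' @rdname accessors
setMethod("genomeSeq", "GenomeRecord", function(x) x@seq)
#' @rdname accessors
setMethod("genomeFeatures", "GenomeRecord", function(x) x@features)

#' @rdname accessors
setMethod("regionLengths", "Quadripartite", function(x)
  c(lsc = sum(width(x@lsc)), irb = sum(width(x@irb)),
    ssc = sum(width(x@ssc)), ira = sum(width(x@ira))))
#' @rdname accessors
setMethod("junctions", "Quadripartite", function(x) x@junctions)

#' @rdname accessors
setMethod("motifs", "RepeatSet", function(x) x@motifs)
#' @rdname accessors
setMethod("genomeId", "RepeatSet", function(x) x@genomeId)

#' @rdname accessors
setMethod("characterStates", "CharacterMatrix", function(x) x@mat)
#' @rdname accessors
setMethod("taxa", "CharacterMatrix", function(x) rownames(x@mat))

#' @rdname accessors
setMethod("distances", "DistanceSummary", function(x) x@dist)

#' @rdname accessors
setMethod("truthLog", "PlastomeSimulation", function(x) x@truth)
#' @rdname accessors
setMethod("trueAlignment", "PlastomeSimulation", function(x) x@alignment)
#' @rdname accessors
setMethod("leafRecords", "PlastomeSimulation", function(x) x@records)

#' Construct a CharacterMatrix
#'
#' @param mat character matrix with taxon rownames
#' @param type "binary", "dna" or "mixed"; guessed from the states when NULL
#' @return a \linkS4class{CharacterMatrix}
#' @export
characterMatrix <- function(mat, type = NULL) {
  mat <- toupper(mat)
  if (is.null(type)) {
    st <- setdiff(unique(as.vector(mat)), c("?", "-", "N"))
    type <- if (all(st %in% c("0", "1"))) "binary"
      else if (all(st %in% DNA_BASES)) "dna" else "mixed"
  }
  new("CharacterMatrix", mat = mat, type = type)
}
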