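#' Accessors for lactopep S4 containers
#'
#' `records()` returns the identification-record data.frame of a
#' [SampleSet-class]; `strainNames()` its strain labels and
#' `replicateCounts()` the declared replicates per strain. `entries()` and
#' `provenance()` access a [CuratedDB-class]; `profileCounts()` and
#' `profileIntensity()` the tracks of a [ResidueProfile-class], and
#' `accession()` its protein label.
#'
#' @param x a lactopep S4 object.
#' @return The slot content (data.frame, character or numeric vector, list).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @rdname accessors
#' @export
setMethod("records", "SampleSet", function(x) x@records)

#' @rdname accessors
#' @export
setGeneric("strainNames", function(x) standardGeneric("strainNames"))
#' @rdname accessors
#' @export
setMethod("strainNames", "SampleSet", function(x) names(x@replicateCount))

#' @rdname accessors
#' @export
setGeneric("replicateCounts", function(x) standardGeneric("replicateCounts"))
#' @rdname accessors
#' @export
setMethod("replicateCounts", "SampleSet", function(x) x@replicateCount)

#' @rdname accessors
#' @export
setGeneric("entries", function(x) standardGeneric("entries"))
#' @rdname accessors
#' @export
setMethod("entries", "CuratedDB", function(x) x@entries)

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setMethod("provenance", "CuratedDB", function(x) x@provenance)

#' @rdname accessors
#' @export
setGeneric("accession", function(x) standardGeneric("accession"))
#' @rdname accessors
#' @export
setMethod("accession", "ResidueProfile", function(x) x@accession)

#' @rdname accessors
#' @export
setGeneric("profileCounts", function(x) standardGeneric("profileCounts"))
#' @rdname accessors
#' @export
setMethod("profileCounts", "ResidueProfile", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("profileIntensity", function(x) standardGeneric("profileIntensity"))
#' @rdname accessors
#' @export
setMethod("profileIntensity", "ResidueProfile", function(x) x@intensitySum)
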