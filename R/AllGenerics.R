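#' @include AllClasses.R
NULL

#' Accessors for actinovar result objects
#'
#' Small accessor generics so slot layout stays an implementation detail.
#'
#' @param x an actinovar S4 object.
#' @return The requested component (numeric scalar, vector, matrix or
#'   data.frame depending on the accessor and class).
#' @name accessors
#' @aliases counts scope lagTime vmax tau reactionOrder hc50 hillCoef tm
#'   rmsd rotation category asaClass records fullSequence
NULL

#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
#' @rdname accessors
#' @export
setGeneric("scope", function(x) standardGeneric("scope"))
#' @rdname accessors
#' @export
setGeneric("lagTime", function(x) standardGeneric("lagTime"))
#' @rdname accessors
#' @export
setGeneric("vmax", function(x) standardGeneric("vmax"))
#' @rdname accessors
#' @export
setGeneric("tau", function(x) standardGeneric("tau"))
#' @rdname accessors
#' @export
setGeneric("reactionOrder", function(x) standardGeneric("reactionOrder"))
#' @rdname accessors
#' @export
setGeneric("hc50", function(x) standardGeneric("hc50"))
#' @rdname accessors
#' @export
setGeneric("hillCoef", function(x) standardGeneric("hillCoef"))
#' @rdname accessors
#' @export
setGeneric("tm", function(x) standardGeneric("tm"))
#' @rdname accessors
#' @export
setGeneric("rmsd", function(x) standardGeneric("rmsd"))
#' @rdname accessors
#' @export
setGeneric("rotation", function(x) standardGeneric("rotation"))
#' @rdname accessors
#' @export
setGeneric("category", function(x) standardGeneric("category"))
#' @rdname accessors
#' @export
setGeneric("asaClass", function(x) standardGeneric("asaClass"))
#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @rdname accessors
#' @export
setGeneric("fullSequence", function(x) standardGeneric("fullSequence"))

#' @rdname accessors
setMethod("counts", "CrossTab", function(x) x@counts)
#' @rdname accessors
setMethod("scope", "CrossTab", function(x) x@scope)
#' @rdname accessors
setMethod("lagTime", "KineticsResult", function(x) x@lagTime)
#' @rdname accessors
setMethod("vmax", "KineticsResult", function(x) x@vmax)
#' @rdname accessors
setMethod("tau", "PowerLawFit", function(x) x@tau)
#' @rdname accessors
setMethod("reactionOrder", "PowerLawFit", function(x) x@exponent)
#' @rdname accessors
setMethod("hc50", "HillFit", function(x) x@hc50)
#' @rdname accessors
setMethod("hillCoef", "HillFit", function(x) x@hillN)
#' @rdname accessors
setMethod("tm", "TmResult", function(x) x@tm)
#' @rdname accessors
setMethod("rmsd", "SuperpositionResult", function(x) x@rmsd)
#' @rdname accessors
setMethod("rotation", "SuperpositionResult", function(x) x@rotation)
#' @rdname accessors
setMethod("category", "ConservationMap",
          function(x) setNames(x@category, x@position))
#' @rdname accessors
setMethod("asaClass", "ASATable",
          function(x) setNames(factor(x@data$asa_class, levels = .ASA_LEVELS),
                               x@data$resno))
#' @rdname accessors
setMethod("records", "ResidueProfile", function(x) x@records)
#' @rdname accessors
setMethod("records", "ASATable", function(x) x@data)
#' @rdname accessors
setMethod("fullSequence", "MatureSequence", function(x) x@full)
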