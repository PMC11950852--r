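## Generics and accessors. Slot access from user code goes through these.

#' @name accessors
#' @title Accessor generics
#' @description Accessors for the package's S4 containers.
#' @param object an object of one of the package's S4 classes.
#' @param x an object of one of the package's S4 classes.
#' @return the corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("ka", function(object) standardGeneric("ka"))
#' @rdname accessors
#' @export
setGeneric("kd", function(object) standardGeneric("kd"))
#' @rdname accessors
#' @export
setGeneric("speciesTable", function(object) standardGeneric("speciesTable"))
#' @rdname accessors
#' @export
setGeneric("backgroundTable", function(object) standardGeneric("backgroundTable"))
#' @rdname accessors
#' @export
setGeneric("totalMolecules", function(object) standardGeneric("totalMolecules"))
#' @rdname accessors
#' @export
setGeneric("readCounts", function(object) standardGeneric("readCounts"))
#' @rdname accessors
#' @export
setGeneric("totalReads", function(object) standardGeneric("totalReads"))
#' @rdname accessors
#' @export
setGeneric("recoveryRate", function(object) standardGeneric("recoveryRate"))
#' @rdname accessors
#' @export
setGeneric("roundResults", function(object) standardGeneric("roundResults"))
#' @rdname accessors
#' @export
setGeneric("readTables", function(object) standardGeneric("readTables"))
#' @rdname accessors
#' @export
setGeneric("families", function(object) standardGeneric("families"))
#' @rdname accessors
#' @export
setGeneric("singletons", function(object) standardGeneric("singletons"))
#' @rdname accessors
#' @export
setGeneric("consensusMotifs", function(object) standardGeneric("consensusMotifs"))
#' @rdname accessors
#' @export
setGeneric("membership", function(object) standardGeneric("membership"))

#' Equilibrium dissociation constant
#'
#' \eqn{K_D = k_d / k_a}, in molar units.
#'
#' @param object a [KineticParams] or [FamilyKinetics] object.
#' @return dissociation constant in M.
#' @examples
#' dissociationConstant(KineticParams(ka = 2.44e5, kd = 51.8e-3)) # ~2.12e-7 M
#' @export
setGeneric("dissociationConstant",
           function(object) standardGeneric("dissociationConstant"))

#' Round summary of a campaign
#'
#' @param object a [CampaignResult].
#' @return data.frame with columns `round`, `input`, `recovered`,
#'   `recoveryRate`.
#' @export
setGeneric("roundSummary", function(object) standardGeneric("roundSummary"))
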