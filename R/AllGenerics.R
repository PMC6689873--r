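#' @rdname Molecule-accessors
#' @export
setGeneric("smiles", function(x) standardGeneric("smiles"))

#' @rdname Molecule-accessors
#' @export
setGeneric("inchi", function(x) standardGeneric("inchi"))

#' @rdname Molecule-accessors
#' @export
setGeneric("inchikey", function(x) standardGeneric("inchikey"))

#' @rdname Molecule-accessors
#' @export
setGeneric("molFormula", function(x) standardGeneric("molFormula"))

#' @rdname Molecule-accessors
#' @export
setGeneric("exactMass", function(x) standardGeneric("exactMass"))

#' @rdname Molecule-accessors
#' @export
setGeneric("alogp", function(x) standardGeneric("alogp"))

#' @rdname Molecule-accessors
#' @export
setGeneric("molLabel", function(x) standardGeneric("molLabel"))

#' @rdname MetabolicTree-accessors
#' @export
setGeneric("treeNodes", function(x) standardGeneric("treeNodes"))

#' @rdname MetabolicTree-accessors
#' @export
setGeneric("treeEdges", function(x) standardGeneric("treeEdges"))

#' @rdname MetabolicTree-accessors
#' @export
setGeneric("rootMolecule", function(x) standardGeneric("rootMolecule"))

#' @rdname Knowledgebase-accessors
#' @export
setGeneric("kbRules", function(x) standardGeneric("kbRules"))

#' @rdname Knowledgebase-accessors
#' @export
setGeneric("kbEnzymes", function(x) standardGeneric("kbEnzymes"))

#' @rdname Knowledgebase-accessors
#' @export
setGeneric("kbPrecedence", function(x) standardGeneric("kbPrecedence"))

#' @rdname Knowledgebase-accessors
#' @export
setGeneric("kbPathways", function(x) standardGeneric("kbPathways"))

#' @rdname Knowledgebase-accessors
#' @export
setGeneric("kbRecords", function(x) standardGeneric("kbRecords"))
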