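#' Element-wise sum of grid-registered fields
#'
#' Superposes fields defined on identical grids (e.g. power deposition of
#' several applicators).  Order-independent; grids must match exactly.
#'
#' @param x a [ScalarField-class] or a list of them.
#' @param ... further `ScalarField`s.
#' @return a [ScalarField-class] with the element-wise sum.
#' @export
setGeneric("superpose", function(x, ...) standardGeneric("superpose"))

#' @rdname VoxelGrid-class
#' @param x object carrying a grid.
#' @export
setGeneric("voxelGrid", function(x) standardGeneric("voxelGrid"))

#' Extract the value array of a field
#' @param x a [ScalarField-class].
#' @return the 3D numeric array of voxel values.
#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))

#' Extract the label array of an anatomy model
#' @param x an [AnatomyModel-class].
#' @return integer 3D array of label codes.
#' @export
setGeneric("anatomyLabels", function(x) standardGeneric("anatomyLabels"))

#' Extract the named structure masks of an anatomy model
#' @param x an [AnatomyModel-class].
#' @return named list of logical arrays.
#' @export
setGeneric("anatomyStructures", function(x) standardGeneric("anatomyStructures"))

#' Extract the tissue-property table of an anatomy model
#' @param x an [AnatomyModel-class].
#' @return named list of [TissueProperties-class].
#' @export
setGeneric("tissueTable", function(x) standardGeneric("tissueTable"))
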