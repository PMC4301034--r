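#' Accessors for the pipeline containers
#'
#' Small generic accessors in place of direct slot access.
#'
#' @param x an object from this package.
#' @return the slot content named by the accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("stackValues", function(x) standardGeneric("stackValues"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("stackOrigin", function(x) standardGeneric("stackOrigin"))
#' @rdname accessors
#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))
#' @rdname accessors
#' @export
setGeneric("tissueLabels", function(x) standardGeneric("tissueLabels"))
#' @rdname accessors
#' @export
setGeneric("nonunionMask", function(x) standardGeneric("nonunionMask"))
#' @rdname accessors
#' @export
setGeneric("youngsModulus", function(x) standardGeneric("youngsModulus"))
#' @rdname accessors
#' @export
setGeneric("poissonRatio", function(x) standardGeneric("poissonRatio"))
#' @rdname accessors
#' @export
setGeneric("nodeCount", function(x) standardGeneric("nodeCount"))
#' @rdname accessors
#' @export
setGeneric("elementCount", function(x) standardGeneric("elementCount"))
#' @rdname accessors
#' @export
setGeneric("dofCount", function(x) standardGeneric("dofCount"))
#' @rdname accessors
#' @export
setGeneric("vonMises", function(x) standardGeneric("vonMises"))
#' @rdname accessors
#' @export
setGeneric("scaledStress", function(x) standardGeneric("scaledStress"))
#' @rdname accessors
#' @export
setGeneric("trajectory", function(x) standardGeneric("trajectory"))

#' Coarsen an image or label volume
#'
#' @param x an \linkS4class{ImageStack} or \linkS4class{LabelVolume}.
#' @param spec a \linkS4class{CoarseningSpec}.
#' @return an object of the same class on the coarser grid.
#' @export
setGeneric("coarsen", function(x, spec) standardGeneric("coarsen"))

#' Crop a fraction of slices from each end of the long axis
#'
#' @param x an \linkS4class{ImageStack} or \linkS4class{LabelVolume}.
#' @param proximalFraction,distalFraction fractions in [0, 1) of slices to
#'   remove from the top (high z) and bottom (low z); must sum to < 1.
#' @return the cropped object with adjusted origin.
#' @export
setGeneric("cropEpiphyses",
  function(x, proximalFraction = 0.15, distalFraction = 0.15)
    standardGeneric("cropEpiphyses"))

setMethod("stackValues", "ImageStack", function(x) x@values)
setMethod("voxelSpacing", "ImageStack", function(x) x@spacing)
setMethod("voxelSpacing", "LabelVolume", function(x) x@spacing)
setMethod("voxelSpacing", "MaterialMap", function(x) x@labels@spacing)
setMethod("voxelSpacing", "VoxelMesh", function(x) x@spacing)
setMethod("stackOrigin", "ImageStack", function(x) x@origin)
setMethod("stackOrigin", "LabelVolume", function(x) x@origin)
setMethod("gridDims", "ImageStack", function(x) dim(x@values))
setMethod("gridDims", "LabelVolume", function(x) dim(x@labels))
setMethod("gridDims", "MaterialMap", function(x) dim(x@E))
setMethod("tissueLabels", "LabelVolume", function(x) x@labels)
setMethod("tissueLabels", "MaterialMap", function(x) x@labels@labels)
setMethod("nonunionMask", "LabelVolume", function(x) x@nonunion)
setMethod("nonunionMask", "MaterialMap", function(x) x@labels@nonunion)
setMethod("youngsModulus", "MaterialMap", function(x) x@E)
setMethod("youngsModulus", "VoxelMesh", function(x) x@E)
setMethod("poissonRatio", "MaterialMap", function(x) x@nu)
setMethod("poissonRatio", "VoxelMesh", function(x) x@nu)
setMethod("nodeCount", "VoxelMesh", function(x) nrow(x@nodes))
setMethod("elementCount", "VoxelMesh", function(x) nrow(x@elems))
setMethod("dofCount", "VoxelMesh", function(x) linearHexDOF(nrow(x@nodes)))
setMethod("vonMises", "StressField", function(x) x@vonMises)
setMethod("scaledStress", "StressField", function(x) x@scaled)
setMethod("trajectory", "OptimizationResult", function(x) x@steps)

#' Degrees of freedom of a linear hexahedral mesh
#'
#' Linear (trilinear) hexahedral elements carry three displacement unknowns
#' per node, so a mesh with n nodes has 3n degrees of freedom.
#'
#' @param nNodes node count.
#' @return integer DOF count.
#' @examples
#' linearHexDOF(381343)  # 1144029
#' @export
linearHexDOF <- function(nNodes) 3L * as.integer(nNodes)

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@values)
  cat(sprintf("ImageStack: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(object@spacing), collapse = " x ")))
  cat(sprintf("  gray range [%.1f, %.1f]\n",
              min(object@values), max(object@values)))
})

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@labels)
  cat(sprintf("LabelVolume: %d x %d x %d voxels\n", d[1], d[2], d[3]))
  tab <- tabulate(object@labels + 1L, nbins = 5L)
  names(tab) <- TISSUE_CLASSES
  print(tab)
  cat(sprintf("  nonunion cells: %d\n", sum(object@nonunion)))
})

setMethod("show", "VoxelMesh", function(object) {
  cat(sprintf("VoxelMesh: %d elements, %d nodes, %d DOF\n",
              nrow(object@elems), nrow(object@nodes),
              3L * nrow(object@nodes)))
  cat(sprintf("  implant elements: %d, nonunion elements: %d\n",
              sum(object@implant), sum(object@nonunion)))
})

setMethod("show", "StressField", function(object) {
  cat(sprintf("StressField: %d elements, max von Mises %.4g Pa\n",
              nrow(object@tensor), max(object@vonMises)))
  if (!is.na(object@referenceMax))
    cat(sprintf("  scaled by reference %.4g Pa (max scaled %.2f)\n",
                object@referenceMax, max(object@scaled)))
})

setMethod("show", "OptimizationResult", function(object) {
  cat(sprintf("OptimizationResult (%s): %d steps\n", object@status,
              sum(!is.na(object@steps$reduction))))
  cat(sprintf("  total reduction %.1f%%, remaining %.1f%% of %d cells\n",
              object@totalReduction, object@remainingFraction,
              object@initialCells))
})
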