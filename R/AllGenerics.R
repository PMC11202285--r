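#' @import methods
NULL

#' Access the agent state matrix
#' @param x an \code{AgentGrid} or \code{GrowthRun}.
#' @return integer matrix of \code{\link{agentStates}} codes.
#' @export
setGeneric("states", function(x) standardGeneric("states"))

#' Access pixel size
#' @param x an object with a spatial lattice.
#' @return pixel pitch (um for agent/nutrient lattices, mm for images).
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' Access a concentration lattice
#' @param x a \code{NutrientField}.
#' @return numeric matrix of concentrations.
#' @export
setGeneric("concentration", function(x) standardGeneric("concentration"))

#' Unitless diffusion number D*dt/dx^2 of an explicit scheme
#' @param x a \code{NutrientField} or \code{BioParams}.
#' @param ... molecule selector for \code{BioParams}.
#' @return the unitless coefficient(s); must not exceed 0.25.
#' @export
setGeneric("diffusionNumber", function(x, ...) standardGeneric("diffusionNumber"))

#' Image values of a pSUV or reconstructed image
#' @param x a \code{PSUVImage} or \code{ReconImage}.
#' @return numeric matrix.
#' @export
setGeneric("imageValues", function(x) standardGeneric("imageValues"))

#' @rdname states
#' @export
setMethod("states", "AgentGrid", function(x) x@states)
#' @rdname states
#' @export
setMethod("states", "GrowthRun", function(x) x@finalGrid@states)

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "AgentGrid", function(x) x@pixelSize)
#' @rdname pixelSize
#' @export
setMethod("pixelSize", "NutrientField", function(x) x@dx)
#' @rdname pixelSize
#' @export
setMethod("pixelSize", "PSUVImage", function(x) x@pixelSize)
#' @rdname pixelSize
#' @export
setMethod("pixelSize", "ReconImage", function(x) x@pixelSize)

#' @rdname concentration
#' @export
setMethod("concentration", "NutrientField", function(x) x@conc)

#' @rdname diffusionNumber
#' @export
setMethod("diffusionNumber", "NutrientField", function(x) {
  dx_cm <- x@dx * 1e-4
  x@D * x@dt / dx_cm^2
})

#' @rdname diffusionNumber
#' @export
setMethod("diffusionNumber", "BioParams", function(x, ...) {
  dx_cm <- x@pixelSize * 1e-4
  c(oxygen  = x@DOxygen  * x@dtDiffusion / dx_cm^2,
    glucose = x@DGlucose * x@dtDiffusion / dx_cm^2)
})

#' @rdname imageValues
#' @export
setMethod("imageValues", "PSUVImage", function(x) x@values)
#' @rdname imageValues
#' @export
setMethod("imageValues", "ReconImage", function(x) x@values)

setMethod("show", "AgentGrid", function(object) {
  s <- object@states
  cnt <- table(factor(s, levels = agentStates, labels = names(agentStates)))
  cat(sprintf("AgentGrid %d x %d pixels (%.0f um pitch, %.1f x %.1f mm)\n",
              nrow(s), ncol(s), object@pixelSize,
              nrow(s) * object@pixelSize / 1e3, ncol(s) * object@pixelSize / 1e3))
  for (nm in names(cnt)) cat(sprintf("  %-15s %d\n", nm, cnt[[nm]]))
  cat(sprintf("  tumor diameter  %.3f mm\n", tumorDiameter(object)))
})

setMethod("show", "NutrientField", function(object) {
  cat(sprintf("NutrientField <%s> %d x %d, D = %.3g cm^2/s, dx = %g um, dt = %g s (alpha = %.4f)\n",
              object@molecule, nrow(object@conc), ncol(object@conc),
              object@D, object@dx, object@dt, diffusionNumber(object)))
  cat(sprintf("  concentration: mean %.4g, range [%.4g, %.4g]\n",
              mean(object@conc), min(object@conc), max(object@conc)))
})

setMethod("show", "PhenotypeConfig", function(object) {
  cat(sprintf("PhenotypeConfig%s: density %g /mm^2 (%s), vessel removal %g, ATP death exponent %g, O2 exponent %g, seed %d\n",
              if (length(object@name)) paste0(" '", object@name, "'") else "",
              object@vesselDensity, object@vesselPattern,
              object@vesselRemovalProb, object@necrosisExponentAtp,
              object@necrosisExponentO2, object@seed))
})

setMethod("show", "GrowthRun", function(object) {
  cat(sprintf("GrowthRun [%s]: %g h simulated, %d snapshots, final diameter %.2f mm\n",
              object@status, object@hours, length(object@snapshots),
              tumorDiameter(object@finalGrid)))
})

setMethod("show", "ReconImage", function(object) {
  cat(sprintf("ReconImage %d x %d (%.2f mm pixels, %.2f mm FWHM, nominal NSTD %.0f%%), mean pSUV %.3f, lesion pixels %d\n",
              nrow(object@values), ncol(object@values), object@pixelSize,
              object@fwhm, 100 * object@noiseNstd, mean(object@values),
              sum(object@lesionMask)))
})

setMethod("show", "GLCM", function(object) {
  cat(sprintf("GLCM: %d gray levels, distance %g, %s\n", object@nLevels,
              object@distance,
              if (object@merged) "direction-merged (4 x 2D)" else "single direction"))
})
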