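#' Agent state codes
#'
#' Integer codes used on the agent lattice. Exactly one agent occupies each
#' 20 x 20 um pixel: a blood vessel cross-section, a normal (healthy) cell,
#' or a tumor cell in one of three metabolic states.
#'
#' @format Named integer vector of length 5.
#' @export
agentStates <- c(
  VESSEL          = 1L,
  NORMAL          = 2L,
  TUMOR_NORMOXIC  = 3L,
  TUMOR_HYPOXIC   = 4L,
  TUMOR_NECROTIC  = 5L
)

#' RGB palette used for agent-map TIFF export
#'
#' The palette is a package convention (vessel red, normal white, normoxic
#' tumor green, hypoxic tumor blue, necrotic black); the TIFF reader inverts
#' it exactly.
#'
#' @format 5 x 3 integer matrix of 0-255 RGB rows, named by state.
#' @export
agentPalette <- matrix(
  c(255L,   0L,   0L,
    255L, 255L, 255L,
      0L, 128L,   0L,
      0L,   0L, 255L,
      0L,   0L,   0L),
  ncol = 3, byrow = TRUE,
  dimnames = list(names(agentStates), c("r", "g", "b"))
)

#' AgentGrid: lattice of cellular agents
#'
#' One categorical agent per pixel on a square lattice of configurable pitch
#' (20 um by default). Necrotic pixels never revert to a viable state within
#' a run.
#'
#' @slot states integer matrix of \code{\link{agentStates}} codes.
#' @slot pixelSize pixel pitch in micrometers.
#' @export
setClass("AgentGrid",
  representation(states = "matrix", pixelSize = "numeric"),
  prototype(pixelSize = 20)
)

setValidity("AgentGrid", function(object) {
  s <- object@states
  if (!is.integer(s)) return("states must be an integer matrix")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    return("pixelSize must be a single positive number")
  bad <- !(s %in% agentStates)
  if (any(bad)) return("states contains codes outside agentStates")
  TRUE
})

#' NutrientField: concentration lattice co-registered with an AgentGrid
#'
#' @slot conc concentration matrix (oxygen in mmHg, glucose in mol/L).
#' @slot molecule "oxygen" or "glucose".
#' @slot D diffusion coefficient, cm^2/s.
#' @slot dx lattice pitch, micrometers.
#' @slot dt diffusion time step, seconds.
#' @export
setClass("NutrientField",
  representation(conc = "matrix", molecule = "character", D = "numeric",
                 dx = "numeric", dt = "numeric")
)

setValidity("NutrientField", function(object) {
  if (any(object@conc < 0)) return("concentrations must be non-negative")
  if (!object@molecule %in% c("oxygen", "glucose"))
    return("molecule must be 'oxygen' or 'glucose'")
  a <- diffusionNumber(object)
  if (a > 0.25)
    return(sprintf("unitless diffusion number %.4f for %s exceeds the explicit-scheme stability bound 0.25",
                   a, object@molecule))
  TRUE
})

#' PhenotypeConfig: the varied microparameters of a simulated tumor phenotype
#'
#' @slot vesselDensity vessels per mm^2 (validated to the physiological
#'   20-100 range by default; see \code{validateDensity=FALSE} in
#'   \code{\link{phenotypeConfig}} to lift it).
#' @slot vesselRemovalProb probability that a dividing tumor cell replaces a
#'   vessel when no normal-cell neighbor exists.
#' @slot vesselPattern "random" or "uniform".
#' @slot necrosisExponentAtp exponent x of the ATP death law 1 - R^x.
#' @slot necrosisExponentO2 exponent of the oxygen death law (1 in all presets).
#' @slot seed integer RNG seed.
#' @slot name optional preset label.
#' @export
setClass("PhenotypeConfig",
  representation(vesselDensity = "numeric", vesselRemovalProb = "numeric",
                 vesselPattern = "character", necrosisExponentAtp = "numeric",
                 necrosisExponentO2 = "numeric", seed = "integer",
                 name = "character")
)

setValidity("PhenotypeConfig", function(object) {
  if (object@vesselDensity <= 0) return("vesselDensity must be positive")
  if (object@vesselRemovalProb < 0 || object@vesselRemovalProb > 1)
    return("vesselRemovalProb must lie in [0, 1]")
  if (!object@vesselPattern %in% c("random", "uniform"))
    return("vesselPattern must be 'random' or 'uniform'")
  if (object@necrosisExponentAtp <= 0 || object@necrosisExponentO2 <= 0)
    return("necrosis exponents must be positive")
  TRUE
})

#' BioParams: biological constants shared by all phenotypes
#'
#' Defaults reproduce the model's fixed biological parameter set: diffusion
#' coefficients, vascular concentrations, per-class metabolic rates, necrosis
#' thresholds, the hypoxia band and the time discretization. Per-class rate
#' vectors are named \code{c(normoxic=, hypoxic=, normal=)} and are in
#' mol/min/cell.
#'
#' @slot DOxygen,DGlucose diffusion coefficients, cm^2/s.
#' @slot vesselO2 vascular oxygen, mmHg.
#' @slot vesselGlucose vascular glucose, mol/L.
#' @slot vmaxO2 per-class constant oxygen consumption, mol/min/cell.
#' @slot vmaxGlucose per-class Michaelis-Menten maximum, mol/min/cell.
#' @slot kmGlucose Michaelis constant for glucose, mol/L.
#' @slot deathAtpRate ATP-production necrosis threshold, mol/min/cell.
#' @slot deathO2Percent oxygen necrosis threshold, percent O2.
#' @slot hypoxiaBandPercent closed hypoxia band, percent O2.
#' @slot divisionInterval mean division interval under normoxia, hours.
#' @slot dtCell agent time step, hours.
#' @slot dtDiffusion diffusion time step, seconds.
#' @slot pixelSize lattice pitch, micrometers.
#' @slot mmHgPerPercent conversion, mmHg per percent O2 (760 mmHg total).
#' @slot o2Solubility Henry-law solubility of oxygen in tissue,
#'   mol/(L*mmHg), used to convert molar consumption to mmHg/s.
#' @slot pixelDepth effective slab depth of the 2D model, micrometers; the
#'   per-pixel volume is pixelSize^2 * pixelDepth.
#' @slot atpPerGlucoseGlycolysis ATP yield of glycolysis per glucose.
#' @slot atpAerobicFactor coefficient of the oxygen term of the ATP rate
#'   (27/5: aerobic yield ~27 ATP/glucose at 5 O2 per glucose... kept as a
#'   single named constant).
#' @export
setClass("BioParams",
  representation(DOxygen = "numeric", DGlucose = "numeric",
                 vesselO2 = "numeric", vesselGlucose = "numeric",
                 vmaxO2 = "numeric", vmaxGlucose = "numeric",
                 kmGlucose = "numeric", deathAtpRate = "numeric",
                 deathO2Percent = "numeric", hypoxiaBandPercent = "numeric",
                 divisionInterval = "numeric", dtCell = "numeric",
                 dtDiffusion = "numeric", pixelSize = "numeric",
                 mmHgPerPercent = "numeric", o2Solubility = "numeric",
                 pixelDepth = "numeric", atpPerGlucoseGlycolysis = "numeric",
                 atpAerobicFactor = "numeric")
)

setValidity("BioParams", function(object) {
  for (nm in c("vmaxO2", "vmaxGlucose")) {
    v <- slot(object, nm)
    if (!all(c("normoxic", "hypoxic", "normal") %in% names(v)))
      return(sprintf("%s must be named c(normoxic=, hypoxic=, normal=)", nm))
    if (any(v < 0)) return(sprintf("%s rates must be non-negative", nm))
  }
  dx_cm <- object@pixelSize * 1e-4
  for (D in c(object@DOxygen, object@DGlucose)) {
    a <- D * object@dtDiffusion / dx_cm^2
    if (a > 0.25)
      return(sprintf("diffusion number %.4f exceeds stability bound 0.25; reduce dtDiffusion", a))
  }
  if (length(object@hypoxiaBandPercent) != 2L ||
      diff(object@hypoxiaBandPercent) <= 0)
    return("hypoxiaBandPercent must be an increasing pair")
  TRUE
})

#' GrowthRun: result of a longitudinal growth simulation
#'
#' @slot config the \code{PhenotypeConfig} used.
#' @slot bio the \code{BioParams} used.
#' @slot snapshots list of AgentGrid snapshots.
#' @slot snapshotTimes biological times (hours) of the snapshots.
#' @slot log data.frame with one row per biological hour (time, state counts,
#'   diameter, field summaries).
#' @slot finalGrid AgentGrid at termination.
#' @slot finalO2,finalGlucose NutrientField at termination.
#' @slot status "complete", "extinct" or "max-hours".
#' @slot hours biological hours simulated.
#' @slot rngState RNG state at termination (for bit-identical resume).
#' @export
setClass("GrowthRun",
  representation(config = "PhenotypeConfig", bio = "BioParams",
                 snapshots = "list", snapshotTimes = "numeric",
                 log = "data.frame", finalGrid = "AgentGrid",
                 finalO2 = "NutrientField", finalGlucose = "NutrientField",
                 status = "character", hours = "numeric", rngState = "integer")
)

#' PSUVImage: cell-scale pseudo-SUV lattice
#'
#' @slot values pSUV matrix (0 necrotic, 1 normal/vessel, 8 normoxic tumor,
#'   12 hypoxic tumor at cell scale).
#' @slot pixelSize pixel size in millimeters.
#' @export
setClass("PSUVImage",
  representation(values = "matrix", pixelSize = "numeric")
)

#' ReconImage: reconstructed PET-like image
#'
#' @slot values reconstructed pSUV matrix (68 x 68 by default).
#' @slot pixelSize reconstruction pixel size, mm (0.58).
#' @slot fwhm end-to-end system resolution, mm (2.35).
#' @slot noiseNstd nominal noise level as NSTD fraction (0 = noise-free).
#' @slot lesionMask logical matrix of in-lesion pixels (may be empty).
#' @export
setClass("ReconImage",
  representation(values = "matrix", pixelSize = "numeric", fwhm = "numeric",
                 noiseNstd = "numeric", lesionMask = "matrix")
)

setValidity("ReconImage", function(object) {
  if (any(object@values < 0)) return("reconstructed values must be non-negative")
  TRUE
})

#' GLCM: direction-merged gray-level co-occurrence matrix
#'
#' @slot matrix square probability matrix over gray levels (sums to 1,
#'   symmetric).
#' @slot nLevels number of gray levels.
#' @slot distance pixel offset distance.
#' @slot merged TRUE when the four 2D directions were pooled before
#'   normalization.
#' @export
setClass("GLCM",
  representation(matrix = "matrix", nLevels = "integer", distance = "numeric",
                 merged = "logical")
)

setValidity("GLCM", function(object) {
  m <- object@matrix
  if (nrow(m) != ncol(m)) return("GLCM must be square")
  if (any(m < 0)) return("GLCM entries must be non-negative")
  if (abs(sum(m) - 1) > 1e-8) return("GLCM must be normalized to sum 1")
  if (max(abs(m - t(m))) > 1e-12) return("GLCM must be symmetric")
  TRUE
})
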