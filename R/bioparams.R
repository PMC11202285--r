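#' Biological constants of the growth model
#'
#' Returns the fixed biological parameter set shared by all phenotypes:
#' nutrient diffusion coefficients, vascular concentrations, per-class
#' metabolic rates, necrosis thresholds, the hypoxia band, the division
#' interval and the two time discretizations (1 h agent steps, 30 ms
#' diffusion steps). Any value can be overridden by name.
#'
#' Unit conventions: oxygen is tracked in mmHg with 1\% O2 = 7.6 mmHg and
#' Henry-law solubility \code{o2Solubility} converting molar consumption into
#' mmHg/s; glucose is tracked in mol/L. Per-cell molar rates become
#' concentration sinks through the effective pixel volume
#' \code{pixelSize^2 * pixelDepth} (a unit-depth slab equal to the cell size).
#'
#' @param ... named overrides of any slot of \code{\linkS4class{BioParams}}.
#' @return a validated \code{BioParams} object.
#' @examples
#' bio <- bioParams()
#' diffusionNumber(bio)  # both molecules below the 0.25 stability bound
#' @export
bioParams <- function(...) {
  obj <- new("BioParams",
    DOxygen        = 1.65e-5,   # cm^2/s
    DGlucose       = 2.7e-6,    # cm^2/s
    vesselO2       = 50,        # mmHg
    vesselGlucose  = 5e-3,      # mol/L
    vmaxO2         = c(normoxic = 4e-15, hypoxic = 2e-15, normal = 2.5e-18),
    vmaxGlucose    = c(normoxic = 5e-14, hypoxic = 1.02e-13, normal = 5e-15),
    kmGlucose      = 5e-4,      # mol/L; the printed KM has rate units and
                                # cannot be used as a concentration
    deathAtpRate   = 2.57e-14,  # mol ATP/min/cell
    deathO2Percent = 0.08,      # % O2
    hypoxiaBandPercent = c(0.08, 0.5),
    divisionInterval = 24,      # h
    dtCell         = 1,         # h
    dtDiffusion    = 0.03,      # s
    pixelSize      = 20,        # um
    mmHgPerPercent = 7.6,       # 760 mmHg total pressure
    o2Solubility   = 1.3e-6,    # mol/(L*mmHg), O2 in tissue at 37 C
    pixelDepth     = 20,        # um
    atpPerGlucoseGlycolysis = 2,
    atpAerobicFactor = 27 / 5
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% slotNames(obj)) stop("unknown BioParams field: ", nm)
    slot(obj, nm) <- dots[[nm]]
  }
  validObject(obj)
  obj
}

#' Derived thresholds in field units
#'
#' Converts the percent-O2 thresholds of \code{BioParams} into mmHg and the
#' per-minute ATP threshold into the quantities the cell engine compares
#' against.
#'
#' @param bio a \code{BioParams}.
#' @return list with \code{o2NecrosismmHg}, \code{hypoxiaBandmmHg} (length 2),
#'   \code{divisionRefmmHg} (oxygen at which division probability saturates,
#'   the upper hypoxia bound), \code{pDivMax} (per-hour probability) and
#'   \code{atpThreshold} (mol/min/cell).
#' @export
bioThresholds <- function(bio) {
  list(
    o2NecrosismmHg  = bio@deathO2Percent * bio@mmHgPerPercent,
    hypoxiaBandmmHg = bio@hypoxiaBandPercent * bio@mmHgPerPercent,
    divisionRefmmHg = bio@hypoxiaBandPercent[2] * bio@mmHgPerPercent,
    pDivMax         = bio@dtCell / bio@divisionInterval,
    atpThreshold    = bio@deathAtpRate
  )
}

# effective pixel volume in liters
pixelVolumeL <- function(bio) {
  (bio@pixelSize * 1e-6)^2 * (bio@pixelDepth * 1e-6) * 1e3  # m^3 -> L
}

# per-cell molar rate (mol/min/cell) -> concentration rate per second, in the
# bookkeeping units of the molecule (mmHg/s for oxygen, mol/L/s for glucose)
molarRateToConcRate <- function(rate, bio, molecule) {
  r <- rate / 60 / pixelVolumeL(bio)      # mol/L/s
  if (molecule == "oxygen") r <- r / bio@o2Solubility
  r
}
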