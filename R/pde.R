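#' Create a nutrient concentration field co-registered with an agent grid
#'
#' Initialized uniformly at the vascular concentration unless \code{init} is
#' given. Oxygen is tracked in mmHg, glucose in mol/L.
#'
#' @param molecule "oxygen" or "glucose".
#' @param dims (rows, cols) of the lattice; a scalar is squared.
#' @param bio a \code{BioParams}.
#' @param init optional initial concentration matrix.
#' @param dt diffusion time step in seconds (default \code{bio@dtDiffusion}).
#' @return a \code{NutrientField}.
#' @export
nutrientField <- function(molecule = c("oxygen", "glucose"), dims,
                          bio = bioParams(), init = NULL,
                          dt = bio@dtDiffusion) {
  molecule <- match.arg(molecule)
  if (length(dims) == 1L) dims <- c(dims, dims)
  cv <- if (molecule == "oxygen") bio@vesselO2 else bio@vesselGlucose
  conc <- if (is.null(init)) matrix(cv, dims[1], dims[2]) else init
  D <- if (molecule == "oxygen") bio@DOxygen else bio@DGlucose
  new("NutrientField", conc = conc, molecule = molecule, D = D,
      dx = bio@pixelSize, dt = dt)
}

# per-pixel maximum sink rate in field units per second; the cell-class map
# of per-class Vmax values converted through the pixel volume (and Henry
# solubility for oxygen). Vessels and necrotic pixels consume nothing.
consumptionVmaxField <- function(grid, bio, molecule) {
  v <- if (molecule == "oxygen") bio@vmaxO2 else bio@vmaxGlucose
  lut <- numeric(5)
  lut[agentStates[["NORMAL"]]]         <- v[["normal"]]
  lut[agentStates[["TUMOR_NORMOXIC"]]] <- v[["normoxic"]]
  lut[agentStates[["TUMOR_HYPOXIC"]]]  <- v[["hypoxic"]]
  out <- matrix(molarRateToConcRate(lut[grid@states], bio, molecule),
                nrow(grid@states), ncol(grid@states))
  out
}

#' Cellular consumption rate field
#'
#' The signed consumption term f of the reaction-diffusion equation,
#' evaluated at the field's current concentrations: for glucose the
#' Michaelis-Menten rate -Vmax [S]/(KM + [S]) with class-specific Vmax; for
#' oxygen the class-specific constant -Vmax (KM negligible against tissue
#' oxygen). Necrotic and vessel pixels consume nothing. Rates are expressed
#' as concentration change per second in the field's units (mmHg/s or
#' mol/L/s) via the effective per-pixel volume.
#'
#' @param grid an \code{AgentGrid} co-registered with \code{field}.
#' @param field a \code{NutrientField}.
#' @param bio a \code{BioParams}.
#' @return matrix of signed rates (<= 0 everywhere).
#' @export
consumptionField <- function(grid, field, bio = bioParams()) {
  if (!all(dim(grid@states) == dim(field@conc)))
    stop("agent grid and nutrient field are not co-registered")
  if (any(field@conc < 0)) stop("negative concentrations in input field")
  vmax <- consumptionVmaxField(grid, bio, field@molecule)
  if (field@molecule == "glucose") {
    -vmax * field@conc / (bio@kmGlucose + field@conc)
  } else {
    -vmax
  }
}

#' One explicit diffusion step
#'
#' A single forward-time centered-space update with the 5-point Laplacian
#' and periodic boundaries, followed by clamping vessel pixels to the
#' vascular concentration (Dirichlet sources) and flooring at zero.
#'
#' @param field a \code{NutrientField}.
#' @param consumption signed rate matrix from \code{\link{consumptionField}}
#'   (concentration units per second).
#' @param vessel logical matrix of vessel pixels (or NULL for none).
#' @param bio a \code{BioParams} (vascular concentrations).
#' @return the updated \code{NutrientField}.
#' @export
diffusionStep <- function(field, consumption = NULL, vessel = NULL,
                          bio = bioParams()) {
  a <- diffusionNumber(field)
  if (a > 0.25)
    stop(sprintf("%s: unitless diffusion number %.4f exceeds the stability bound 0.25",
                 field@molecule, a))
  sink <- if (is.null(consumption)) matrix(0, nrow(field@conc), ncol(field@conc))
          else -consumption
  conc <- ftcs_step_cpp(field@conc, sink, a, field@dt)
  if (!is.null(vessel)) {
    cv <- if (field@molecule == "oxygen") bio@vesselO2 else bio@vesselGlucose
    conc[vessel] <- cv
  }
  conc[conc < 0] <- 0
  field@conc <- conc
  field
}

#' Relax a nutrient field to steady state
#'
#' Iterates explicit diffusion steps (with Michaelis-Menten consumption
#' re-evaluated at the current concentration each step and vessels clamped)
#' until the maximum fractional change per step falls below \code{tol}, or
#' \code{maxIter} is reached (warning, not fatal). Optionally restricts the
#' sweep to a sub-box with frozen boundary values, which is exact up to the
#' diffusive screening length and is used to re-relax locally perturbed
#' fields cheaply.
#'
#' @param field a \code{NutrientField}.
#' @param grid the co-registered \code{AgentGrid}.
#' @param bio a \code{BioParams}.
#' @param tol relative per-step change tolerance (default 1e-5).
#' @param maxIter iteration cap.
#' @param box optional integer c(r0, r1, c0, c1) sub-box (1-based, inclusive).
#' @param quiet suppress the non-convergence warning.
#' @return list with \code{field}, \code{iters} and \code{converged}.
#' @export
relaxToSteadyState <- function(field, grid, bio = bioParams(), tol = 1e-5,
                               maxIter = 200000L, box = NULL, quiet = FALSE) {
  if (tol <= 0) stop("tol must be positive")
  a <- diffusionNumber(field)
  if (a > 0.25)
    stop(sprintf("%s: unitless diffusion number %.4f exceeds the stability bound 0.25",
                 field@molecule, a))
  vmax <- consumptionVmaxField(grid, bio, field@molecule)
  km <- if (field@molecule == "glucose") bio@kmGlucose else 0
  cv <- if (field@molecule == "oxygen") bio@vesselO2 else bio@vesselGlucose
  vm <- vesselMask(grid)
  if (is.null(box)) {
    r <- relax_ftcs_cpp(field@conc, as.numeric(vmax), km, as.logical(vm), cv,
                        a, field@dt, tol, as.integer(maxIter))
    field@conc <- r$conc
  } else {
    r <- relax_ftcs_box_cpp(field@conc, as.numeric(vmax), km, as.logical(vm),
                            cv, a, field@dt, tol, as.integer(maxIter),
                            as.integer(box[1] - 1L), as.integer(box[2] - 1L),
                            as.integer(box[3] - 1L), as.integer(box[4] - 1L))
    field@conc <- r$conc
  }
  if (!r$converged && !quiet)
    warning(sprintf("%s relaxation did not reach tol %.1e within %d steps",
                    field@molecule, tol, maxIter))
  list(field = field, iters = r$iters, converged = r$converged)
}
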