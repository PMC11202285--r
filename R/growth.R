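#' Simulate longitudinal tumor growth
#'
#' Orchestrates a full growth run: vessels are placed, the oxygen and
#' glucose fields are relaxed to steady state, a single normoxic tumor cell
#' is seeded at the center, and then each biological hour the fields are
#' re-relaxed and every viable tumor cell is updated
#' (survival -> oxygenation -> division) until the equivalent-circle tumor
#' diameter reaches \code{stopDiameter}, the tumor goes extinct, or
#' \code{maxHours} elapses. Agent-grid snapshots are stored every
#' \code{snapshotInterval} hours.
#'
#' Two numerical accelerations, both documented in the methods vignette,
#' keep desk-scale runs fast without changing the computed steady states:
#' the relaxation time step is chosen at the stability bound (the FTCS fixed
#' point is independent of dt), and hourly re-relaxations sweep only a box
#' around the tumor with frozen boundary values (exact up to the diffusive
#' screening length), warm-started from the previous hour and capped at
#' \code{hourlyMaxIter} steps so residuals carry over quasi-statically.
#'
#' @param config a \code{PhenotypeConfig} (its seed fixes the trajectory).
#' @param bio a \code{BioParams}.
#' @param stopDiameter stop when the tumor reaches this diameter, mm.
#' @param dims grid dimensions (scalar or pair), default 2000.
#' @param snapshotInterval hours between stored snapshots (default 10).
#' @param maxHours hard cap on simulated hours.
#' @param tol steady-state relaxation tolerance.
#' @param hourlyMaxIter per-hour relaxation cap per field.
#' @param boxMargin margin (pixels) of the relaxation box around the tumor.
#' @param accelerate relax at the stability-bound time step (default TRUE).
#' @param verbose print progress every 100 h.
#' @return a \code{GrowthRun}.
#' @examples
#' \donttest{
#' run <- runGrowth(phenotypePreset("A", seed = 7), stopDiameter = 0.5,
#'                  dims = 150)
#' tumorDiameter(run@finalGrid)
#' }
#' @export
runGrowth <- function(config, bio = bioParams(), stopDiameter = 10,
                      dims = c(2000L, 2000L), snapshotInterval = 10,
                      maxHours = 500000, tol = 1e-5, hourlyMaxIter = 400L,
                      boxMargin = 30L, accelerate = TRUE, verbose = FALSE) {
  if (length(dims) == 1L) dims <- c(dims, dims)
  worldMm <- min(dims) * bio@pixelSize / 1e3
  if (stopDiameter > worldMm)
    stop("stopDiameter exceeds the physical grid size")
  grid <- placeVessels(config, bio, dims)
  dtO2  <- if (accelerate) 0.2 * (bio@pixelSize * 1e-4)^2 / bio@DOxygen  else bio@dtDiffusion
  dtGlu <- if (accelerate) 0.2 * (bio@pixelSize * 1e-4)^2 / bio@DGlucose else bio@dtDiffusion
  o2  <- nutrientField("oxygen",  dims, bio, dt = dtO2)
  glu <- nutrientField("glucose", dims, bio, dt = dtGlu)
  o2  <- relaxToSteadyState(o2,  grid, bio, tol = tol, quiet = TRUE)$field
  glu <- relaxToSteadyState(glu, grid, bio, tol = tol, quiet = TRUE)$field
  grid <- seedTumor(grid)
  run <- new("GrowthRun", config = config, bio = bio,
             snapshots = list(grid), snapshotTimes = 0,
             log = data.frame(), finalGrid = grid, finalO2 = o2,
             finalGlucose = glu, status = "running", hours = 0,
             rngState = .Random.seed)
  if (stopDiameter <= tumorDiameter(grid)) {
    run@status <- "complete"
    return(run)
  }
  continueGrowth(run, stopDiameter, snapshotInterval, maxHours, tol,
                 hourlyMaxIter, boxMargin, verbose)
}

# shared hourly loop used by runGrowth and resumeGrowth
continueGrowth <- function(run, stopDiameter, snapshotInterval, maxHours,
                           tol, hourlyMaxIter, boxMargin, verbose = FALSE) {
  grid <- run@finalGrid; o2 <- run@finalO2; glu <- run@finalGlucose
  bio <- run@bio; config <- run@config
  dims <- dim(grid@states)
  hour <- run@hours
  logs <- if (nrow(run@log)) list(run@log) else list()
  snaps <- run@snapshots; snapTimes <- run@snapshotTimes
  tumorCodes <- agentStates[c("TUMOR_NORMOXIC", "TUMOR_HYPOXIC", "TUMOR_NECROTIC")]
  status <- "running"
  repeat {
    if (hour >= maxHours) { status <- "max-hours"; break }
    box <- tumorBox(grid, boxMargin)
    o2  <- relaxToSteadyState(o2,  grid, bio, tol = tol,
                              maxIter = hourlyMaxIter, box = box,
                              quiet = TRUE)$field
    glu <- relaxToSteadyState(glu, grid, bio, tol = tol,
                              maxIter = hourlyMaxIter, box = box,
                              quiet = TRUE)$field
    grid <- updateAgents(grid, o2, glu, config, bio)
    hour <- hour + bio@dtCell
    st <- grid@states
    cnt <- tabulate(st, nbins = 5L)
    dia <- tumorDiameter(grid)
    tm <- st >= tumorCodes[1]
    logs[[length(logs) + 1L]] <- data.frame(
      time = hour, nVessel = cnt[1], nNormal = cnt[2], nNormoxic = cnt[3],
      nHypoxic = cnt[4], nNecrotic = cnt[5], diameter = dia,
      tumorO2 = if (any(tm)) mean(o2@conc[tm]) else NA_real_,
      tumorGlucose = if (any(tm)) mean(glu@conc[tm]) else NA_real_)
    if (hour %% snapshotInterval == 0) {
      snaps[[length(snaps) + 1L]] <- grid
      snapTimes <- c(snapTimes, hour)
    }
    if (verbose && hour %% 100 == 0)
      message(sprintf("t = %5.0f h  diameter %.2f mm  viable %d  necrotic %d",
                      hour, dia, cnt[3] + cnt[4], cnt[5]))
    if (cnt[3] + cnt[4] == 0) { status <- "extinct"; break }
    if (dia >= stopDiameter) { status <- "complete"; break }
  }
  # fields are stored exactly as used for the last update so that a resumed
  # run continues bit-identically; measureTissueConcentrations re-relaxes
  # against the terminal grid without touching the stored state
  run@snapshots <- snaps
  run@snapshotTimes <- snapTimes
  run@log <- do.call(rbind, logs)
  run@finalGrid <- grid
  run@finalO2 <- o2
  run@finalGlucose <- glu
  run@status <- status
  run@hours <- hour
  run@rngState <- .Random.seed
  run
}

# bounding box of tumor pixels, widened by margin and clipped to the grid
tumorBox <- function(grid, margin) {
  tm <- which(tumorMask(grid), arr.ind = TRUE)
  if (nrow(tm) == 0) return(NULL)
  d <- dim(grid@states)
  r0 <- max(1L, min(tm[, 1]) - margin); r1 <- min(d[1], max(tm[, 1]) + margin)
  c0 <- max(1L, min(tm[, 2]) - margin); c1 <- min(d[2], max(tm[, 2]) + margin)
  if ((r1 - r0 + 1L) * (c1 - c0 + 1L) >= 0.75 * prod(d)) return(NULL)
  c(r0, r1, c0, c1)
}

#' Resume a growth run bit-identically
#'
#' Restores the RNG state serialized in the run and continues the hourly
#' loop; a run stopped at \code{maxHours} and resumed reproduces an
#' uninterrupted run exactly.
#'
#' @param run a \code{GrowthRun}.
#' @param stopDiameter target diameter, mm.
#' @param snapshotInterval,maxHours,tol,hourlyMaxIter,boxMargin as in
#'   \code{\link{runGrowth}}.
#' @return a \code{GrowthRun}.
#' @export
resumeGrowth <- function(run, stopDiameter, snapshotInterval = 10,
                         maxHours = 500000, tol = 1e-5, hourlyMaxIter = 400L,
                         boxMargin = 30L) {
  assign(".Random.seed", run@rngState, envir = globalenv())
  continueGrowth(run, stopDiameter, snapshotInterval, maxHours, tol,
                 hourlyMaxIter, boxMargin)
}

#' Mean nutrient concentrations by tissue compartment
#'
#' Averages the steady-state oxygen and glucose fields over normal-tissue
#' pixels and over tumor pixels (all tumor states) at the end of a run.
#'
#' @param run a finished \code{GrowthRun}.
#' @param rerelax relax the stored fields against the terminal grid before
#'   averaging (default TRUE; the stored fields lag the terminal grid by the
#'   final hourly update).
#' @return data.frame with one row: normalO2 (mmHg), normalGlucose (mM),
#'   tumorO2 (mmHg), tumorGlucose (mM).
#' @export
measureTissueConcentrations <- function(run, rerelax = TRUE) {
  grid <- run@finalGrid
  o2 <- run@finalO2; glu <- run@finalGlucose
  if (rerelax) {
    o2  <- relaxToSteadyState(o2,  grid, run@bio, maxIter = 50000L,
                              quiet = TRUE)$field
    glu <- relaxToSteadyState(glu, grid, run@bio, maxIter = 50000L,
                              quiet = TRUE)$field
  }
  st <- grid@states
  nm <- st == agentStates[["NORMAL"]]
  tm <- st >= agentStates[["TUMOR_NORMOXIC"]]
  data.frame(
    normalO2      = mean(o2@conc[nm]),
    normalGlucose = mean(glu@conc[nm]) * 1e3,
    tumorO2       = if (any(tm)) mean(o2@conc[tm]) else NA_real_,
    tumorGlucose  = if (any(tm)) mean(glu@conc[tm]) * 1e3 else NA_real_)
}
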