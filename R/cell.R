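#' ATP production rate from nutrient consumption rates
#'
#' Total ATP production combines glycolysis (2 ATP per glucose) with the
#' oxygen-limited aerobic contribution: f_ATP = 2 f_G + (27/5) f_O, where
#' f_G and f_O are the magnitudes of the glucose and oxygen consumption
#' rates (mol/min/cell).
#'
#' @param fG glucose consumption rate magnitude, mol/min/cell.
#' @param fO oxygen consumption rate magnitude, mol/min/cell.
#' @param bio a \code{BioParams} (yield coefficients).
#' @return ATP production rate, mol/min/cell.
#' @examples
#' atpRate(5e-14, 4e-15)  # normoxic tumor cell at saturating glucose
#' @export
atpRate <- function(fG, fO, bio = bioParams()) {
  if (any(fG < 0) || any(fO < 0)) stop("consumption rate magnitudes must be >= 0")
  bio@atpPerGlucoseGlycolysis * fG + bio@atpAerobicFactor * fO
}

#' Necrosis probability from a depleted local quantity
#'
#' p = 1 - (local/threshold)^x when the local value is below its threshold,
#' and 0 otherwise; clipped to [0, 1]. Applied to the local oxygen
#' concentration (exponent 1) and to the ATP production rate (phenotype
#' exponent).
#'
#' @param localValue local oxygen concentration or ATP rate.
#' @param thresholdValue the necrosis threshold (> 0).
#' @param x positive exponent.
#' @return probability in [0, 1].
#' @examples
#' deathProbability(0.5, 1, 2)  # R = 0.5, x = 2 -> 0.75
#' @export
deathProbability <- function(localValue, thresholdValue, x) {
  if (thresholdValue <= 0) stop("thresholdValue must be positive")
  if (x <= 0) stop("exponent must be positive")
  p <- ifelse(localValue >= thresholdValue, 0,
              1 - (pmax(localValue, 0) / thresholdValue)^x)
  pmin(pmax(p, 0), 1)
}

#' One survival evaluation for a viable tumor cell
#'
#' Evaluates the death probability twice -- local oxygen against its
#' threshold with the oxygen exponent, then the ATP production rate against
#' its threshold with the phenotype exponent -- drawing one uniform number
#' per criterion. Either success renders the cell necrotic.
#'
#' @param localO2 local oxygen, mmHg.
#' @param fAtp ATP production rate, mol/min/cell.
#' @param config a \code{PhenotypeConfig} (exponents).
#' @param bio a \code{BioParams} (thresholds).
#' @return TRUE if the cell survives, FALSE if it becomes necrotic.
#' @export
survivalStep <- function(localO2, fAtp, config, bio = bioParams()) {
  th <- bioThresholds(bio)
  pO <- deathProbability(localO2, th$o2NecrosismmHg, config@necrosisExponentO2)
  if (pO > 0 && stats::runif(1) < pO) return(FALSE)
  pA <- deathProbability(fAtp, th$atpThreshold, config@necrosisExponentAtp)
  if (pA > 0 && stats::runif(1) < pA) return(FALSE)
  TRUE
}

#' Oxygenation state of a surviving tumor cell
#'
#' Hypoxic iff the local oxygen lies in the closed band 0.08-0.5\% O2
#' (0.608-3.8 mmHg at the fixed 7.6 mmHg per percent conversion); above the
#' band the cell is normoxic. Transitions are bidirectional. Survivors below
#' the band (death already evaluated) are classified hypoxic.
#'
#' @param localO2 local oxygen, mmHg.
#' @param bio a \code{BioParams}.
#' @return "normoxic" or "hypoxic".
#' @export
oxygenationState <- function(localO2, bio = bioParams()) {
  band <- bioThresholds(bio)$hypoxiaBandmmHg
  ifelse(localO2 > band[2], "normoxic", "hypoxic")
}

#' Hourly division probability
#'
#' p = (1/24) * min(1, O2 / ref) per hour, where ref is the normoxia
#' threshold (0.5\% O2 = 3.8 mmHg): every normoxic cell divides on average
#' once per 24 h, and hypoxic cells scale linearly with local oxygen.
#'
#' @param localO2 local oxygen, mmHg.
#' @param bio a \code{BioParams}.
#' @return probability per hour.
#' @export
divisionProbability <- function(localO2, bio = bioParams()) {
  th <- bioThresholds(bio)
  th$pDivMax * pmin(1, pmax(localO2, 0) / th$divisionRefmmHg)
}

#' Place a daughter cell in the Moore neighborhood
#'
#' Called after a successful division draw. The daughter takes a uniformly
#' chosen NORMAL neighbor among the 8-neighborhood; when none exists, a
#' VESSEL neighbor is replaced with probability \code{vesselRemovalProb};
#' otherwise the division is lost. Daughters inherit the parent's state.
#' Neighborhoods wrap periodically.
#'
#' @param grid an \code{AgentGrid}.
#' @param i,j parent pixel (1-based).
#' @param config a \code{PhenotypeConfig}.
#' @return the (possibly) modified \code{AgentGrid}.
#' @export
attemptDivision <- function(grid, i, j, config) {
  st <- grid@states
  nr <- nrow(st); nc <- ncol(st)
  parent <- st[i, j]
  if (!parent %in% agentStates[c("TUMOR_NORMOXIC", "TUMOR_HYPOXIC")])
    stop("parent pixel is not a viable tumor cell")
  off <- cbind(rep(-1:1, each = 3), rep(-1:1, times = 3))
  off <- off[!(off[, 1] == 0 & off[, 2] == 0), ]
  ii <- ((i + off[, 1] - 1) %% nr) + 1
  jj <- ((j + off[, 2] - 1) %% nc) + 1
  ns <- st[cbind(ii, jj)]
  normals <- which(ns == agentStates[["NORMAL"]])
  vessels <- which(ns == agentStates[["VESSEL"]])
  if (length(normals) > 0) {
    k <- normals[sample.int(length(normals), 1)]
    st[ii[k], jj[k]] <- parent
  } else if (length(vessels) > 0 && stats::runif(1) < config@vesselRemovalProb) {
    k <- vessels[sample.int(length(vessels), 1)]
    st[ii[k], jj[k]] <- parent
  }
  grid@states <- st
  grid
}

#' One biological hour of agent updates
#'
#' Applies, to every viable tumor cell in a random permutation, the decision
#' sequence survival -> oxygenation classification -> division. Metabolic
#' rates are read from the (steady-state) nutrient fields; division requires
#' both oxygen and ATP at or above their necrosis thresholds and succeeds
#' with the oxygen-scaled hourly probability, placing the daughter per
#' \code{\link{attemptDivision}}. Normal cells and vessels are passive;
#' necrotic pixels never revert. Daughters created this hour are not
#' re-processed until the next hour. All draws come from R's RNG, so
#' \code{set.seed} fixes the trajectory bit-identically.
#'
#' @param grid an \code{AgentGrid}.
#' @param o2,glucose \code{NutrientField}s at steady state.
#' @param config a \code{PhenotypeConfig}.
#' @param bio a \code{BioParams}.
#' @return the updated \code{AgentGrid}.
#' @export
updateAgents <- function(grid, o2, glucose, config, bio = bioParams()) {
  th <- bioThresholds(bio)
  st <- update_agents_cpp(
    grid@states, o2@conc, glucose@conc,
    th$o2NecrosismmHg, th$hypoxiaBandmmHg[1], th$hypoxiaBandmmHg[2],
    th$divisionRefmmHg, th$pDivMax, th$atpThreshold,
    config@necrosisExponentAtp, config@necrosisExponentO2,
    bio@vmaxO2[c("normoxic", "hypoxic")],
    bio@vmaxGlucose[c("normoxic", "hypoxic")],
    bio@kmGlucose, bio@atpAerobicFactor, config@vesselRemovalProb)
  grid@states <- st
  grid
}

#' Waiting times to first division under full oxygenation
#'
#' Simulates independent fully oxygenated cells with unlimited free
#' neighbors, drawing the hourly division Bernoulli trial until first
#' success. The waiting time is geometric with mean equal to the division
#' interval (24 h).
#'
#' @param n number of cells.
#' @param localO2 local oxygen, mmHg (default: vascular, i.e. fully
#'   oxygenated).
#' @param bio a \code{BioParams}.
#' @param maxHours cap per cell.
#' @return integer vector of first-division times in hours.
#' @export
divisionWaitTimes <- function(n, localO2 = bioParams()@vesselO2,
                              bio = bioParams(), maxHours = 10000L) {
  p <- divisionProbability(localO2, bio)
  vapply(seq_len(n), function(k) {
    for (h in seq_len(maxHours)) if (stats::runif(1) < p) return(h)
    NA_integer_
  }, integer(1))
}
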