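#' Create a vascularized normal-tissue lattice
#'
#' Fills a grid with normal cells and places vessel cross-sections either at
#' uniform-random distinct pixels ("random" pattern) or on a square lattice
#' at spacing 1/sqrt(density) with independent per-vessel jitter of +/- 25\%
#' of the spacing ("uniform" pattern; collisions re-jittered). The vessel
#' count equals \code{round(density * physical area)}. Deterministic given
#' the seed in \code{config}.
#'
#' @param config a \code{PhenotypeConfig}.
#' @param bio a \code{BioParams} (pixel size).
#' @param dims integer (rows, cols); a scalar is squared.
#' @return an \code{AgentGrid}.
#' @examples
#' g <- placeVessels(phenotypePreset("A"), bioParams(), 200)
#' sum(states(g) == agentStates["VESSEL"])  # 100/mm^2 * 16 mm^2 = 1600
#' @export
placeVessels <- function(config, bio = bioParams(), dims = c(2000L, 2000L)) {
  if (length(dims) == 1L) dims <- c(dims, dims)
  dims <- as.integer(dims)
  if (any(dims <= 0)) stop("dims must be positive")
  areaMm2 <- prod(dims) * (bio@pixelSize / 1e3)^2
  nVessel <- round(config@vesselDensity * areaMm2)
  if (nVessel > prod(dims))
    stop("non-physical configuration: vessel count ", nVessel,
         " exceeds pixel count ", prod(dims))
  st <- matrix(agentStates[["NORMAL"]], dims[1], dims[2])
  set.seed(config@seed)
  if (config@vesselPattern == "random") {
    st[sample.int(prod(dims), nVessel)] <- agentStates[["VESSEL"]]
  } else {
    spacingPx <- 1 / sqrt(config@vesselDensity) * 1e3 / bio@pixelSize
    nr <- max(1L, round(dims[1] / spacingPx))
    nc <- max(1L, round(dims[2] / spacingPx))
    base <- expand.grid(i = (seq_len(nr) - 0.5) * dims[1] / nr,
                        j = (seq_len(nc) - 0.5) * dims[2] / nc)
    occupied <- logical(prod(dims))
    for (k in seq_len(nrow(base))) {
      repeat {
        ii <- ((round(base$i[k] + stats::runif(1, -0.25, 0.25) * spacingPx) - 1) %% dims[1]) + 1
        jj <- ((round(base$j[k] + stats::runif(1, -0.25, 0.25) * spacingPx) - 1) %% dims[2]) + 1
        lin <- ii + (jj - 1) * dims[1]
        if (!occupied[lin]) { occupied[lin] <- TRUE; break }
      }
    }
    st[occupied] <- agentStates[["VESSEL"]]
  }
  new("AgentGrid", states = st, pixelSize = bio@pixelSize)
}

#' Seed a single normoxic tumor cell at the center of the grid
#'
#' The center pixel (ceiling of the midpoint on each axis) becomes a
#' normoxic tumor cell. If the center is a vessel it is replaced, with a
#' warning, so that the single initial cell always exists. Idempotent.
#'
#' @param grid an \code{AgentGrid}.
#' @return the modified \code{AgentGrid}.
#' @export
seedTumor <- function(grid) {
  st <- grid@states
  i <- ceiling(nrow(st) / 2); j <- ceiling(ncol(st) / 2)
  if (st[i, j] == agentStates[["VESSEL"]])
    warning("center pixel is a vessel; replaced by the initial tumor cell")
  if (st[i, j] %in% agentStates[c("TUMOR_NORMOXIC", "TUMOR_HYPOXIC", "TUMOR_NECROTIC")])
    return(grid)
  st[i, j] <- agentStates[["TUMOR_NORMOXIC"]]
  grid@states <- st
  grid
}

#' Equivalent-circle tumor diameter
#'
#' Diameter 2*sqrt(A/pi) in millimeters, where A is the physical area of all
#' tumor-state pixels (normoxic + hypoxic + necrotic core).
#'
#' @param grid an \code{AgentGrid}.
#' @return diameter in mm (0 when no tumor pixels).
#' @export
tumorDiameter <- function(grid) {
  n <- sum(grid@states >= agentStates[["TUMOR_NORMOXIC"]])
  aMm2 <- n * (grid@pixelSize / 1e3)^2
  2 * sqrt(aMm2 / pi)
}

# logical mask helpers used across modules
tumorMask  <- function(grid) grid@states >= agentStates[["TUMOR_NORMOXIC"]]
vesselMask <- function(grid) grid@states == agentStates[["VESSEL"]]
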