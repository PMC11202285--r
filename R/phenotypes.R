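#' Construct a phenotype configuration
#'
#' The four microparameters that distinguish simulated tumor phenotypes:
#' vessel density, vessel removal probability, vessel distribution pattern
#' and the exponent of the ATP necrosis law, plus the RNG seed.
#'
#' @param vesselDensity vessels per mm^2.
#' @param vesselRemovalProb probability in [0, 1] that a dividing tumor cell
#'   replaces a neighboring vessel when no normal cell is available.
#' @param vesselPattern "random" (uniform-random distinct pixels) or
#'   "uniform" (jittered square lattice).
#' @param necrosisExponentAtp exponent x of the ATP death probability
#'   1 - R^x.
#' @param necrosisExponentO2 exponent of the oxygen death probability
#'   (1 in all presets).
#' @param seed integer RNG seed.
#' @param name optional label.
#' @param validateDensity enforce the physiological 20-100 per mm^2 range
#'   (default TRUE).
#' @return a \code{PhenotypeConfig}.
#' @export
phenotypeConfig <- function(vesselDensity, vesselRemovalProb,
                            vesselPattern = c("random", "uniform"),
                            necrosisExponentAtp = 2, necrosisExponentO2 = 1,
                            seed = 1L, name = character(0),
                            validateDensity = TRUE) {
  vesselPattern <- match.arg(vesselPattern)
  if (vesselDensity <= 0) stop("vesselDensity must be positive")
  if (validateDensity && (vesselDensity < 20 || vesselDensity > 100))
    stop("vesselDensity outside the physiological range 20-100 per mm^2 ",
         "(use validateDensity = FALSE to override)")
  new("PhenotypeConfig", vesselDensity = vesselDensity,
      vesselRemovalProb = vesselRemovalProb, vesselPattern = vesselPattern,
      necrosisExponentAtp = necrosisExponentAtp,
      necrosisExponentO2 = necrosisExponentO2, seed = as.integer(seed),
      name = name)
}

# the six shipped phenotype parameterizations
.presetTable <- data.frame(
  name    = c("A", "B", "C", "D", "E", "F"),
  density = c(100, 50, 50, 20, 80, 50),
  removal = c(0.05, 0.05, 0.5, 0.05, 0.02, 1),
  pattern = c("random", "uniform", "random", "uniform", "random", "random"),
  expAtp  = c(2, 2, 1, 2, 1, 2),
  stringsAsFactors = FALSE
)

#' Phenotype presets A-F
#'
#' The six shipped tumor phenotype parameterizations. A: dense random
#' vasculature with quadratic ATP death; B: uniform vasculature; C: diffuse,
#' high vessel removal, linear ATP death; D: sparse uniform vasculature;
#' E: dense, low removal, linear ATP death; F: certain vessel removal.
#'
#' @param name one of "A".."F".
#' @param seed RNG seed stored in the config.
#' @return a \code{PhenotypeConfig}.
#' @examples
#' phenotypePreset("A")
#' @export
phenotypePreset <- function(name, seed = 1L) {
  i <- match(toupper(name), .presetTable$name)
  if (is.na(i)) stop("unknown phenotype preset: ", name)
  p <- .presetTable[i, ]
  phenotypeConfig(p$density, p$removal, p$pattern,
                  necrosisExponentAtp = p$expAtp, seed = seed, name = p$name)
}

#' Names of the shipped phenotype presets
#' @return character vector "A".."F".
#' @export
phenotypePresetNames <- function() .presetTable$name

#' Read / write a phenotype configuration as YAML
#'
#' @param config a \code{PhenotypeConfig}.
#' @param path file path.
#' @return \code{readPhenotypeYaml} returns a \code{PhenotypeConfig};
#'   \code{writePhenotypeYaml} returns \code{path} invisibly.
#' @export
writePhenotypeYaml <- function(config, path) {
  yaml::write_yaml(list(
    name = if (length(config@name)) config@name else NULL,
    vessel_density = config@vesselDensity,
    vessel_removal_prob = config@vesselRemovalProb,
    vessel_pattern = config@vesselPattern,
    necrosis_exponent_atp = config@necrosisExponentAtp,
    necrosis_exponent_o2 = config@necrosisExponentO2,
    seed = config@seed
  ), path)
  invisible(path)
}

#' @rdname writePhenotypeYaml
#' @export
readPhenotypeYaml <- function(path) {
  y <- yaml::read_yaml(path)
  phenotypeConfig(y$vessel_density, y$vessel_removal_prob, y$vessel_pattern,
                  necrosisExponentAtp = y$necrosis_exponent_atp,
                  necrosisExponentO2 = if (is.null(y$necrosis_exponent_o2)) 1 else y$necrosis_exponent_o2,
                  seed = if (is.null(y$seed)) 1L else y$seed,
                  name = if (is.null(y$name)) character(0) else y$name)
}

#' Full-scale reference growth times
#'
#' Reference times (days) for the six shipped phenotypes to grow from a
#' single cell to a 1 cm diameter tumor at full scale (2000 x 2000 grid),
#' used to validate scaled runs: growth is linear in time, so scaled runs
#' are compared against these via their diameter-vs-time slope.
#'
#' @return named numeric vector of days, one per preset A-F.
#' @export
growthTimesToOneCmDays <- function() {
  c(A = 96, B = 158, C = 180, D = 258, E = 108, F = 196)
}
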