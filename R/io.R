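#' Write / read an agent map as an RGB TIFF
#'
#' Serializes the agent lattice with the fixed documented palette
#' (\code{\link{agentPalette}}): vessel red, normal white, normoxic tumor
#' green, hypoxic tumor blue, necrotic black. The reader inverts the palette
#' exactly; unknown colors are an error.
#'
#' @param grid an \code{AgentGrid}.
#' @param path output file.
#' @param pixelSize pixel pitch (um) to attach on read.
#' @return \code{writeAgentTiff} returns \code{path} invisibly;
#'   \code{readAgentTiff} returns an \code{AgentGrid}.
#' @export
writeAgentTiff <- function(grid, path) {
  st <- grid@states
  img <- array(0, dim = c(nrow(st), ncol(st), 3))
  for (ch in 1:3)
    img[, , ch] <- matrix(agentPalette[st, ch] / 255, nrow(st), ncol(st))
  tiff::writeTIFF(img, path, compression = "none")
  invisible(path)
}

#' @rdname writeAgentTiff
#' @export
readAgentTiff <- function(path, pixelSize = 20) {
  img <- tiff::readTIFF(path)
  key <- round(img[, , 1] * 255) * 1e6 + round(img[, , 2] * 255) * 1e3 +
         round(img[, , 3] * 255)
  palKey <- agentPalette[, 1] * 1e6 + agentPalette[, 2] * 1e3 + agentPalette[, 3]
  st <- matrix(match(key, palKey), nrow(img), ncol(img))
  if (any(is.na(st))) stop("TIFF contains colors outside the agent palette")
  new("AgentGrid", states = matrix(as.integer(st), nrow(img)),
      pixelSize = pixelSize)
}

#' Dump a concentration lattice as a single-channel float TIFF
#' @param field a \code{NutrientField} (or matrix).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeFieldTiff <- function(field, path) {
  v <- if (is(field, "NutrientField")) field@conc else field
  tiff::writeTIFF(v / max(v, 1e-30), path, bits.per.sample = 32L,
                  compression = "none")
  invisible(path)
}

#' Deterministic small test worlds
#'
#' A registry of fixtures with known ground truth: "disc" (a filled tumor
#' disc of radius 30 pixels in normal tissue, 150 x 150), "two-phase" (half
#' normoxic / half hypoxic tumor block), "uniform-phantom-2.37" (the uniform
#' reference phantom at pSUV 2.37 on the reconstruction grid) and "mini-A"
#' (a 300 x 300 phenotype-A world with vessels placed, seed 1).
#'
#' @param name fixture name.
#' @return an \code{AgentGrid}, or a \code{PSUVImage} for the phantom.
#' @export
makeFixture <- function(name) {
  bio <- bioParams()
  switch(name,
    "disc" = {
      n <- 150L
      st <- matrix(agentStates[["NORMAL"]], n, n)
      ctr <- (n + 1) / 2
      d2 <- (row(st) - ctr)^2 + (col(st) - ctr)^2
      st[d2 <= 30^2] <- agentStates[["TUMOR_NORMOXIC"]]
      new("AgentGrid", states = st, pixelSize = bio@pixelSize)
    },
    "two-phase" = {
      n <- 100L
      st <- matrix(agentStates[["NORMAL"]], n, n)
      st[26:75, 26:50] <- agentStates[["TUMOR_NORMOXIC"]]
      st[26:75, 51:75] <- agentStates[["TUMOR_HYPOXIC"]]
      new("AgentGrid", states = st, pixelSize = bio@pixelSize)
    },
    "uniform-phantom-2.37" = {
      acq <- acquisitionSettings()
      new("PSUVImage", values = matrix(2.37, acq$nPix, acq$nPix),
          pixelSize = acq$pixelMm)
    },
    "mini-A" = seedTumor(placeVessels(phenotypePreset("A", seed = 1L), bio,
                                      c(300L, 300L))),
    # structured 10 mm lesions used by the noise-response checks: texture
    # only survives reconstruction for lesions well above the 2.35 mm
    # resolution, so these are built at the informative size
    "lesion-cored" = lesionPhantom("cored"),
    "lesion-speckled" = lesionPhantom("speckled"),
    "lesion-rimmed" = lesionPhantom("rimmed"),
    stop("unknown fixture: ", name)
  )
}

# 600 x 600 worlds holding a 10 mm diameter tumor with distinct internal
# structure; deterministic (speckle pattern from a fixed local RNG)
lesionPhantom <- function(kind) {
  n <- 600L
  st <- matrix(agentStates[["NORMAL"]], n, n)
  d2 <- (row(st) - 300.5)^2 + (col(st) - 300.5)^2
  tumor <- d2 <= 250^2
  st[tumor] <- agentStates[["TUMOR_NORMOXIC"]]
  if (kind == "cored") {
    st[d2 <= 125^2] <- agentStates[["TUMOR_NECROTIC"]]
    st[d2 > 125^2 & d2 <= 185^2] <- agentStates[["TUMOR_HYPOXIC"]]
  } else if (kind == "speckled") {
    blob <- (sin(row(st) / 6) * cos(col(st) / 7)) > 0.55
    st[tumor & blob] <- agentStates[["TUMOR_NECROTIC"]]
    blob2 <- (cos(row(st) / 9) * sin(col(st) / 5)) > 0.6
    st[tumor & blob2 & !blob] <- agentStates[["TUMOR_HYPOXIC"]]
  } else if (kind == "rimmed") {
    st[d2 > 185^2 & d2 <= 250^2] <- agentStates[["TUMOR_HYPOXIC"]]
  } else stop("unknown lesion phantom: ", kind)
  new("AgentGrid", states = st, pixelSize = 20)
}

#' Export a growth run to disk
#'
#' Writes one RGB TIFF per snapshot, the hourly log as JSONL (one record
#' per biological hour), the resolved phenotype configuration as YAML, and
#' a manifest JSON with an inventory of all written files and their MD5
#' checksums.
#'
#' @param run a \code{GrowthRun}.
#' @param dir output directory (created).
#' @return the manifest, invisibly.
#' @export
exportGrowthRun <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (k in seq_along(run@snapshots)) {
    f <- file.path(dir, sprintf("snapshot_t%06d.tiff", run@snapshotTimes[k]))
    writeAgentTiff(run@snapshots[[k]], f)
    files <- c(files, f)
  }
  logPath <- file.path(dir, "log.jsonl")
  con <- file(logPath, "w")
  for (r in seq_len(nrow(run@log)))
    writeLines(jsonlite::toJSON(as.list(run@log[r, ]), auto_unbox = TRUE,
                                digits = NA), con)
  close(con)
  cfgPath <- file.path(dir, "config.yaml")
  writePhenotypeYaml(run@config, cfgPath)
  files <- c(files, logPath, cfgPath)
  manifest <- list(
    config = list(name = if (length(run@config@name)) run@config@name else NA,
                  seed = run@config@seed),
    status = run@status, hours = run@hours,
    finalDiameterMm = tumorDiameter(run@finalGrid),
    files = data.frame(path = basename(files),
                       md5 = unname(tools::md5sum(files))))
  manifestPath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
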