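# Shared scaled growth runs, computed once per test session. Desk-scale
# study conditions: 250 x 250 grid (5 x 5 mm world), growth stopped at
# 2.0 mm equivalent-circle diameter, one realization per phenotype with
# fixed seeds.
.runCache <- new.env(parent = emptyenv())

scaledRuns <- function(dims = 250L, stopDiameter = 2.0) {
  key <- sprintf("runs_%d_%g", dims, stopDiameter)
  got <- get0(key, envir = .runCache)
  if (!is.null(got)) return(got)
  runs <- lapply(seq_along(phenotypePresetNames()), function(k) {
    nm <- phenotypePresetNames()[k]
    runGrowth(phenotypePreset(nm, seed = 100L + k), stopDiameter = stopDiameter,
              dims = dims, snapshotInterval = 50)
  })
  names(runs) <- phenotypePresetNames()
  assign(key, runs, envir = .runCache)
  runs
}
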