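# Shared fixtures, generated once per test run and memoized. Smaller-than-
# default thorax grids keep the pipeline property tests fast; the acceptance
# tests use the full default phantom.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

smallThorax <- function(noiseSD = 0, posture = "supine", seed = 1L, ...) {
  key <- paste(c("thorax", noiseSD, posture, seed, unlist(list(...))),
               collapse = "_")
  fixture(key, generateThoraxPhantom(
    thoraxTruth(dim = c(48L, 72L, 72L), noiseSD = noiseSD,
                posture = posture, seed = seed, ...)))
}

defaultThorax <- function(noiseSD = 0.02, seed = 1L, ...) {
  key <- paste(c("thoraxFull", noiseSD, seed, unlist(list(...))),
               collapse = "_")
  fixture(key, generateThoraxPhantom(
    thoraxTruth(noiseSD = noiseSD, seed = seed, ...)))
}
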