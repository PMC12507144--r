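# Shared phantom fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# steady (waveform == 1) Poiseuille cylinder, noise-free
steadyTube <- function(spacing = 2.5, length = 80) {
  fixture(sprintf("steady_%g_%g", spacing, length), function() {
    makePhantom(phantomSpec("straight", radius = 10, length = length,
                            vmaxPeak = 1, noiseSD = 0, seed = 1,
                            waveform = 1, dt = 32, spacing = spacing,
                            pwvTrue = 1e5))
  })
}

steadyTubeMesh <- function(spacing = 2.5, length = 80) {
  fixture(sprintf("steadymesh_%g_%g", spacing, length), function() {
    ph <- steadyTube(spacing, length)
    lumenDiameter(extractWall(ph$seg), ph$seg)
  })
}

# pulsatile U-bend with full geometry (mesh, centerline, regions)
ubendPhantom <- function(noiseSD = 0) {
  fixture(sprintf("ubend_%g", noiseSD), function() {
    ph <- makePhantom(phantomSpec("u-bend", radius = 8, length = 30,
                                  bendRadius = 22, vmaxPeak = 1,
                                  noiseSD = noiseSD, seed = 3,
                                  waveform = defaultWaveform(20), dt = 40,
                                  spacing = 2.5))
    ph$geo <- phantomGeometry(ph)
    ph
  })
}

# small healthy cohort + atlas on a shared U-bend template
atlasFixture <- function() {
  fixture("atlas25", function() {
    tmpl <- phantomSpec("u-bend", radius = 8, length = 25, bendRadius = 20,
                        vmaxPeak = 1, noiseSD = 0.05, seed = 100,
                        waveform = defaultWaveform(20), dt = 40,
                        spacing = 2.5)
    cs <- cohortSpec(25, tmpl, vmaxSD = 0.1, seed = 500)
    c(cohortAtlas(cs), list(template = tmpl, cspec = cs))
  })
}

analyticCylinderAxis <- function(ph) {
  g <- ph$truth$layout
  c(g$cx, g$cy) / 1000
}
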