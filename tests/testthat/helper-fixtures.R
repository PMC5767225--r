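# Shared fixtures.  Simulation sizes here are scaled down from the
# generator's 24^3/240 defaults (16^3 grid, shorter series) to keep the
# suite fast; statistical parameters of each tested property (m, alpha,
# effect sizes, thresholds, numbers of runs/seeds) are used as stated.

.fixtureCache <- new.env(parent = emptyenv())

memoFixture <- function(key, fn) {
    if (!exists(key, envir = .fixtureCache))
        assign(key, fn(), envir = .fixtureCache)
    get(key, envir = .fixtureCache)
}

# small config with planted effects in every standard band so that all
# five bands yield clusters: conventional-band effects are also seen by
# slow-5/slow-4 (overlapping bins), plus slow-3 and slow-2 regions
smallEffectConfig <- function(seed = 42L, m = 20L, subjectSd = 1.0,
                              effect = 1.0, nTimepoints = 120L,
                              allBands = FALSE) {
    cfg <- syntheticConfig(shape = c(16L, 16L, 16L),
                           nTimepoints = nTimepoints, nSubjects = m,
                           subjectSd = subjectSd, seed = seed)
    cfg@regions <- lapply(cfg@regions, function(r) { r$effect <- effect; r })
    if (allBands) {
        geo <- pairclass:::.headGeometry(cfg@shape, cfg@voxelSize)
        cfg@regions <- c(cfg@regions, list(
            list(name = "eyeball2", favored = "EO", effect = effect,
                 band = frequencyBand("slow2", 0.198, 0.25),
                 center = geo$eyeCenters[2L, ], radiusMm = 6)))
    }
    cfg
}

smallNullConfig <- function(seed) {
    syntheticConfig(shape = c(16L, 16L, 16L), nTimepoints = 60L,
                    nSubjects = 10L, regions = list(), subjectSd = 0.3,
                    seed = seed)
}

# one moderate dataset reused by several test files
sharedEffectDataset <- function() memoFixture("sharedEffect", function() {
    generatePairedDataset(smallEffectConfig(seed = 42L))
})

# its Monte-Carlo extent threshold at the suite's standard settings
sharedExtentThreshold <- function() memoFixture("sharedExtent", function() {
    monteCarloExtentThreshold(sharedEffectDataset()@mask, fwhmMm = 6,
                              pVoxel = 0.01, alpha = 0.05, nIter = 1000L,
                              seed = 11L)
})

# run one dataset through ALFF -> t -> clusters -> mean features
analyzeDataset <- function(ds, band, extent, method = "mean",
                           pVoxel = 0.01, nDiscard = 10L) {
    maps <- datasetAlffMaps(ds, band, nDiscard = nDiscard)
    tmap <- pairedTMap(maps$mapsC, maps$mapsO, ds@mask)
    cl <- labelClusters(tmap, ds@mask,
                        voxelThresholdFromP(pVoxel, tmap@df), extent)
    list(maps = maps, tmap = tmap, clusters = cl)
}

# a small two-cluster world shared by the feature/classification tests
featureWorld <- function() memoFixture("featureWorld", function() {
    g <- volumeGridCreate(c(12, 12, 12))
    mask <- binaryMask(array(TRUE, c(12, 12, 12)), g)
    tv <- array(0, c(12, 12, 12))
    tv[3:5, 3:5, 3:5] <- 5; tv[8:10, 8:10, 8:10] <- -5
    tm <- new("PairedTMap", grid = g, values = tv, df = 9)
    cl <- labelClusters(tm, mask, 2, 1)
    list(grid = g, mask = mask, clusters = cl)
})

# constant-valued AlffMap on a grid
constantAlffMap <- function(value, grid, band = standardBands("conventional")[[1]]) {
    new("AlffMap", grid = grid, values = array(value, dim = grid@shape),
        band = band, normalized = FALSE)
}

# AlffMap holding given values (array or vector in raster order)
valuesAlffMap <- function(values, grid,
                          band = standardBands("conventional")[[1]]) {
    new("AlffMap", grid = grid, values = array(values, dim = grid@shape),
        band = band, normalized = FALSE)
}
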