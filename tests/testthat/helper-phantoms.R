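# Small shared phantom configurations used across test files. Grids are kept
# small so a full build + entropy pass stays well under a second.

smallInvitro <- function(seed = 1L, cellMelanin = 0, snrDb = Inf,
                         grid = c(4L, 64L, 48L)) {
  invitroPhantomSpec(grid = grid, cellMelanin = cellMelanin,
                     cellTop = 10, cellBottom = 22, membraneTop = 24,
                     membraneBottom = 36, snrDb = snrDb, seed = seed)
}

smallInvivo <- function(seed = 1L, rpeMelanin = 0.8, atrophyRadiusFrac = 0.3,
                        graftRadiusFrac = 0, graftMelanin = 0.8, snrDb = Inf,
                        grid = c(8L, 96L, 64L)) {
  invivoPhantomSpec(grid = grid, rpeMelanin = rpeMelanin,
                    atrophyRadiusFrac = atrophyRadiusFrac,
                    graftRadiusFrac = graftRadiusFrac,
                    graftMelanin = graftMelanin, rpeTop = 32,
                    snrDb = snrDb, seed = seed)
}

# Segment label matrix of the in vivo scene (rpe / atrophic / graft).
segmentMatrixOf <- function(spec) {
  ri <- which(vapply(spec@layers, function(l) l@name, character(1)) == "rpe")
  attr(spec@layers[[ri]]@melanin, "segment")
}
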