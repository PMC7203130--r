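# psoctEntropy

Polarimetric entropy analysis of Jones-matrix PS-OCT volumes: estimating
relative melanin content of the retinal pigment epithelium (RPE) from the
randomness of polarization.

## The problem

Melanin content is a representative feature of healthy RPE, and its granules
scramble the polarization of backscattered light. Polarization-sensitive OCT
(PS-OCT) measures a complex 2x2 Jones matrix per voxel, capturing the
sample's complete polarization response. This package turns such volumes
into quantitative melanin read-outs for two settings:

* **in vitro** — cultured RPE sheets on transwell inserts, where the porous
  membrane is itself strongly depolarizing and must be excluded by geometry;
* **in vivo** — maculae with RPE atrophy and/or a transplanted RPE sheet,
  where the melanin-rich choroid beneath the RPE must be excluded.

It is aimed at researchers in ocular imaging and RPE regenerative medicine
who need an end-to-end, testable reference implementation — including a
seeded phantom simulator, since clinical PS-OCT volumes are not public.

## The statistic

Jones matrices of a local window are vectorized,
`k = (J11, J12, J21, J22)`, and averaged into the coherency (density)
matrix

    rho = sum_i k_i k_i^H / sum_i ||k_i||^2

(4x4, Hermitian, PSD, unit trace; the Cloude–Pottier construction). Its von
Neumann entropy with log base 4,

    H = -sum_i lambda_i log4 lambda_i,

ranges from 0 (completely uniform polarization, rank-1 `rho`) to 1
(completely random polarization, `rho = I/4`). Additive detection noise
inflates `H`; the known noise variance is subtracted from `rho` in
expectation (with PSD re-projection) before the eigen-decomposition, and
noise-dominated voxels are masked. En face maps project `H` along depth
under explicit exclusion rules (above-membrane maximum; ±1-pixel band at
the delineated RPE/graft curve), and ROI statistics relate entropy to
pigmentation.

## Worked example

Simulate a transplanted-macula phantom (intact RPE at melanin 0.8, an
atrophic disc at 0, a graft disc at 0.8), compute the entropy volume, build
the choroid-excluding en face map, and summarise the segments:

```r
library(psoctEntropy)

spec <- invivoPhantomSpec(grid = c(16L, 192L, 72L), rpeMelanin = 0.8,
                          atrophyRadiusFrac = 0.3, graftRadiusFrac = 0.15,
                          rpeTop = 36, snrDb = 20, seed = 42L)
phantom <- buildPhantom(spec)
ev <- entropyVolume(phantom$volume)
ev
#> EntropyVolume: 16 frames x 192 lateral x 72 depth
#>   kernel halfwidths (depth, lateral, frame): 1, 3, 0
#>   valid voxels: 94.4%; noise-corrected: TRUE

map <- enfaceBand(ev, boundaryCurves(phantom$truth))
map
#> EnFaceMap (entropy, rule band_at_delineation): 16 x 192
#>   range 0.0015 .. 0.9564, 0 sentinel positions

rep <- segmentReport(ev, boundaryCurves(phantom$truth), frames = 7:8)
aggregate(cbind(mean, sd) ~ label, rep, mean)
#>      label   mean    sd
#> 1 atrophic 0.0574 0.117
#> 2    graft 0.6497 0.112
#> 3      rpe 0.6390 0.111
```

The atrophic segment (no melanin) sits an order of magnitude below the
intact RPE, and the graft matches the intact RPE at equal melanin — the
pattern expected when a transplanted sheet retains its pigment. `writeEnFaceTiff()` /
`writeEnFacePng()` export the maps; `detectMembraneTop()`,
`enfaceMaxAbove()`, `greyRoiStats()` and `pigmentationEntropyRelation()`
cover the in vitro photograph-versus-entropy comparison.

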