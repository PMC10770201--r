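# slnf

Localization of point-like γ-sources from a single multi-pinhole collimator
image, for radio-guided surgery research — in particular sentinel lymph node
biopsy, where ⁹⁹ᵐTc tracer depots must be located in 3D from the count image
of a stationary γ-detector rather than by sweeping a hand-held audio probe.

## The model

A tungsten plate at `z = 0` carries a set of small pinholes; the pixelated
detector sits behind it and the source volume in front is sampled on a
regular voxel grid. Photons are assumed to travel in straight lines through
the pinhole centers, so the expected detector image of a source distribution
`u ≥ 0` over the `M` voxels is the linear forward model

```
A u = d_proj,      A ∈ {0,1}^(N×M)
```

where `A[i, j] = 1` iff a ray exists from voxel `j` through some pinhole to
pixel `i`. Column `j` of `A` is the binary detector **fingerprint** of a
point source in voxel `j` — one inverted image spot per pinhole.

**SLNF** (sentinel lymph node fingerprinting) localizes a known number of
point sources greedily from the observed image `d_obs`: each round scores
every voxel by the matched-filter correlation

```
C(d_proj, d_obs) = Σ_i d_proj[i] · d_obs[i]
```

(for a binary fingerprint: the counts collected on its pixels), takes the
argmax, then zeroes the selected fingerprint's pixels so the next-strongest
source dominates the following round.

Candidate positions can be ranked before any measurement by the
A-optimal-design **assessability score** of their fingerprint `d`,

```
V(d) = trace( d (dᵀd)⁻² dᵀ ) = 1 / (dᵀd) = 1 / nnz(d),
```

higher score ⇒ fewer informative pixels ⇒ harder to localize.

The package implements the system-matrix construction, a Poisson acquisition
simulator (septal-penetration smear, uniform hot-background volumes, 2×2
binning, 16-bit TIFF I/O), the greedy reconstruction, the assessability
ranking, and an evaluation harness reporting the median and third quartile
of ℓ² localization errors over repeated acquisitions — the protocol is 10
measurements of 8 s exposure per configuration. Independent brute-force
reference implementations (`oracle_*()`) cross-validate every algorithm.

## Worked example

```r
library(slnf)

geom <- fixture_geometry("default")   # reduced 9-pinhole bench geometry
geom
#> <slnf_geometry>
#>   detector:   64 x 128 binned pixels (pitch 0.6 mm), plane at z = -30 mm
#>   collimator: 9 pinholes, plate 60 x 30 mm, penetration 7.5%
#>   grid:       15 x 31 x 56 voxels @ 2 mm (M = 26,040)

sm <- build_system_matrix(geom)
phantom <- fixture_phantom("default") # 3 x 3 vial grid, 20 mm spacing

# two simultaneous 15 MBq sources, 10 Poisson acquisitions of 8 s
stack <- simulate_acquisition(phantom[c(2, 7), ], sm, acquisition_config(seed = 42))
rec <- slnf_reconstruct(stack$images[[1]], sm, n_sources = 2)
tidy(rec)
#> # A tibble: 2 x 7
#>    rank voxel  x_mm  y_mm  z_mm score n_ties
#>   <int> <int> <dbl> <dbl> <dbl> <dbl>  <int>
#> 1     1 22868     0   -20   100  7131      1
#> 2     2 13718     0     0    60  6022      1

match_sources(voxel_to_position(rec),
              as.matrix(stack$truth[, c("x_snap", "y_snap", "z_snap")]))
#> # A tibble: 2 x 3
#>   estimate truth error_mm
#>      <int> <int>    <dbl>
#> 1        1     2        0
#> 2        2     1        0
```

Both sources are recovered at 0 mm error; the stronger-looking fingerprint
(position 7, more counts on its pixels) is extracted first, `score` is the
counts its fingerprint collected, and `n_ties = 1` says the argmax was
unique. Ranking the phantom by expected difficulty:

```r
head(rank_positions(phantom, sm), 3)
#> # A tibble: 3 x 9
#>      id  x_mm  y_mm  z_mm voxel n_pixels score invisible  rank
#>   <int> <dbl> <dbl> <dbl> <int>    <int> <dbl> <lgl>     <int>
#> 1     3     0    20    60 13868        4  0.25 FALSE         1
#> 2     1     0   -20    60 13568        5  0.2  FALSE         2
#> 3     2     0     0    60 13718        5  0.2  FALSE         2
```

Position 3's fingerprint illuminates only 4 pixels, so it carries the least
information and tops the difficulty ranking.

A command-line front end wrapping the same functions ships at
`inst/cli/slnf` (subcommands `geometry`, `build-matrix`, `simulate`,
`reconstruct`, `assess`, `evaluate`, `make-fixtures`).

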