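# capsidlattice

Geometry and sequence analysis for icosahedral virus capsids built from
**pseudo-hexameric trimers** of double jelly-roll (DJR) major capsid
proteins — the architecture of the lipid-containing ssDNA phages of
*Flavobacterium* and of the dsDNA PRD1–adenovirus lineage. It is written
for structural virologists and bioinformaticians who need the *bookkeeping*
side of such structures to be exact and testable: which Caspar–Klug designs
a trimeric building block can occupy, how many sub-particles a localized
reconstruction should produce, what the asymmetric unit contains, and how
integrated relatives of such phages are located in bacterial genomes.

## The models at its core

**Caspar–Klug constraint analysis.** A design indexed by lattice vectors
(h, k) has triangulation number T = h² + hk + k², 12 pentamers and
N = 60(T−1)/6 = 10(T−1) hexagon positions, in class 1 (k = 0), class 2
(skew; handed, h > k > 0 *dextro*) or class 3 (h = k). Two constraints
restrict which designs a trimer can build: a trimer cannot occupy a
hexagon centred on an icosahedral 2-fold axis (geometrically: T even),
and designs whose **hexamer complexity** C^h — the number of distinct
hexamer fold shapes, computed here from the crease pattern icosahedral
edges impose on each hexagonal tile — exceeds 2 are disfavoured. The
smallest surviving designs are T = 3, 7, 9, 13, 21, 25.

**pT = 21 quasi-equivalence.** For (4, 1), the 200 trimers fall into four
orbits (60/60/20/60: peripentonal, two-fold flanking, on-three-fold,
bulk); the asymmetric unit holds (T−1)/2 = 10 MCP monomers = 20 jelly
rolls plus one penton domain = 21 quasi-equivalent building blocks.

**Localized-reconstruction geometry.** A sub-particle at capsid-frame
site S·v (symmetry operator S, unit vector v, radius r) of a particle
with ZYZ Euler matrix A projects at the in-plane part of A·S·(r v), with
orientation A·S·Q (Q the minimal rotation placing v on z) and the
out-of-plane component stored for defocus adjustment. Orbit
deduplication gives 60/20/12 sub-particles per capsid for
general/three-fold/vertex sites. C5 symmetry-relaxation candidate sets
and composite-map stitching transforms round out the geometry.

**Prophage and dif-site scanning.** Loci are called from homology hit
tables (rep-initiator followed by MCP within a gap bound), then refined
by the flanking 28-nt dif palindromes (11-nt XerC arm, central
hexanucleotide, 11-nt XerD arm) that mark XerC/XerD-mediated
integration; conservation profiles (sum-of-pairs identity, z-normalised)
map onto structures via the B-factor column.

All inputs can be simulated: seeded, bit-reproducible particle tables,
genomes with implanted prophage cassettes, and mutated sequence families
with ground truth.

## Worked example

```r
library(capsidlattice)
group <- build_icosahedral_group()

atlas <- capsid_atlas(28, group = group)
atlas[, c("h", "k", "T", "class", "handedness", "hex_on_2fold", "Ch", "allowed")]
#>  h k  T class handedness hex_on_2fold Ch allowed
#>  1 0  1     1    achiral        FALSE  0   FALSE   (no hexamers)
#>  1 1  3     3    achiral        FALSE  1    TRUE
#>  2 0  4     1    achiral         TRUE  1   FALSE   (hexagon on 2-fold)
#>  2 1  7     2     dextro        FALSE  1    TRUE
#>  3 0  9     1    achiral        FALSE  2    TRUE
#>  2 2 12     3    achiral         TRUE  3   FALSE
#>  3 1 13     2     dextro        FALSE  2    TRUE
#>  4 0 16     1    achiral         TRUE  2   FALSE
#>  3 2 19     2     dextro        FALSE  3   FALSE   (complexity > 2)
#>  4 1 21     2     dextro        FALSE  2    TRUE
#>  5 0 25     1    achiral        FALSE  2    TRUE
#>  3 3 27     3    achiral        FALSE  4   FALSE   (Sputnik-type, C^h = 4)
#>  4 2 28     2     dextro         TRUE  3   FALSE
```

The allowed column reads off the headline result: the six smallest
designs available to a pseudo-hexameric trimer are T = 3, 7, 9, 13, 21,
25 — and T = 21 *dextro* (4, 1) is the architecture of the phages this
analysis models. Its bookkeeping:

```r
lat <- build_capsid_lattice(4, 1, group = group)
table(assign_trimer_types(lat, group = group)$trimer_type)
#>  1  2  3  4
#> 60 60 20 60
asymmetric_unit_composition(4, 1)
#> $mcp_monomers 10; $beta_sandwiches 20; $penton_domains 1; $building_blocks 21
```

Sub-particle expansion of a synthetic 6501-particle data set reproduces
the localized-reconstruction counts:

```r
ps <- gen_particle_table(6501, seed = 1)
ax <- symmetry_axes(group)
v5 <- as.numeric(ax[ax$fold == 5, c("x", "y", "z")][1, ])
nrow(expand_subparticles(ps, define_subparticle_vector(v5, 315), group))
#> [1] 78012            # 12 per capsid; a general trimer site gives 390060
```

The numbered scripts under `analysis/` run the full narrative —
`01_capsid_atlas.R` (constraint analysis), `02_t21_capsid.R`
(quasi-equivalence and point model), `03_subparticles.R` (expansion,
defocus, relaxation, stitching), `04_prophage_scan.R` (implant → call →
dif → logo → conservation) — writing tables under `results/`.

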