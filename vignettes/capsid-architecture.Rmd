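---
title: "Capsid architectures for pseudo-hexameric trimers: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Capsid architectures for pseudo-hexameric trimers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capsidlattice)
```

This vignette is the package's own account of the science it implements:
the geometric models, the conventions that every numeric result depends
on, the design choices that were genuinely open, and what the synthetic
data can and cannot show about real data.

## The problem

Many icosahedral viruses -- including the lipid-containing ssDNA phages of
*Flavobacterium* and their dsDNA relatives in the PRD1--adenovirus lineage
-- build their shells not from hexamers but from *pseudo-hexameric
trimers* of a double jelly-roll (DJR) major capsid protein: each monomer
carries two upright beta-sandwiches (V1, V2), so a trimer presents six
quasi-equivalent towers and occupies a hexagonal lattice position. This
substitution has architectural consequences. A trimer has 3-fold internal
symmetry, so it cannot sit on an icosahedral 2-fold axis; and a shell
design that forces its hexagonal building block into many distinct folded
shapes is costly. The package quantifies both constraints over the
Caspar--Klug (CK) design space and provides the supporting machinery:
symmetry groups and orbits, sub-particle geometry for localized
reconstruction, and prophage/dif-site scanning for the genomic side of the
same biology.

## Icosahedral symmetry: convention and construction

All geometry lives in one axis convention, the common cryo-EM "I" (222)
setting: icosahedron vertices at $(0, \pm 1, \pm\varphi)$ and cyclic
permutations, which puts 2-fold axes on x, y and z and a 5-fold axis at
$(0, 1, \varphi)/\lVert\cdot\rVert$. The literature this package leans on
does not fix a setting, so any internally consistent choice is
acceptable; this one is documented in `build_icosahedral_group()$
convention_tag`, and `rot_about_axis()` gives a conversion operator to any
other setting.

The 60 rotation operators are *generated*, not hard-coded: one 5-fold and
one 2-fold generator are closed under multiplication, which only reaches
order 60 if the generators are mutually consistent -- a self-verifying
construction. The test suite additionally brute-forces all 3600 pairwise
products, the determinant of every operator, and the census of 6 five-fold,
10 three-fold and 15 two-fold axes.

Orbits under the group drive all per-capsid copy numbers: a generic
direction has 60 images; a direction on a 3-fold axis 20; on a 5-fold
axis 12; on a 2-fold axis 30. Deduplication of coincident images uses a
relative tolerance of `1e-6` -- far below any physical spacing (the
closest distinct capsomer directions in a T = 148 lattice are separated
by ~0.05 rad) and far above double-precision noise, so the choice is not
delicate.

## Caspar--Klug lattices

A design is indexed by $(h, k)$ with triangulation number
$T = h^2 + hk + k^2$; the face triangle of the icosahedron has corners on
hexagonal-lattice points separated by $(h, k)$. The constructed shell has
12 pentamers (the vertices) and $10(T-1)$ hexamer positions. Class 1
designs have $k = 0$, class 3 $h = k$, class 2 the skew remainder; skew
designs are handed, and following the anchored structural convention the
package calls $h > k > 0$ *dextro* -- the hand observed in the
pT = 21 shells of PM2, FLiP and their ssDNA relatives. Canonical
enumeration (`ck_indices()`) emits $h \ge k$ (the dextro representative);
the laevo partner is its mirror image, and all architecture flags are
mirror-invariant (tested).

The lattice is built once on a reference face and replicated with the 60
operators, so cross-face consistency is inherited from the group rather
than asserted. Axis-coincidence tests ("is any hexamer on a 2-fold?") are
geometric, with tolerance `1e-6` of the unit radius -- exact lattice
points land on axes to machine precision, so again the tolerance carries
no information. Two arithmetic oracles pin the geometry down: a hexamer
sits on a 2-fold iff $T$ is even, and on a 3-fold iff $3 \mid T$; the
suite verifies the geometric tests against both rules for every design up
to $T = 148$.

## Hexamer complexity

The second constraint needs a definition of "how many distinct hexamer
shapes does a design require?" ($C^h$). The source literature reports
values but not a reproducible formula, so the package fixes an
operational definition and calibrates it against every printed value:

* Each hexamer is the hexagonal Voronoi tile of its lattice point on the
  polyhedral shell. Its neighbourhood contains no icosahedral vertex (the
  nearest vertex is a full lattice spacing away, outside the tile's
  circumradius $1/\sqrt{3}$), so the tile unfolds exactly into the plane
  and the icosahedral edges crossing it become straight *creases*.
* A crease is typed combinatorially: a **rim fold** runs along a tile
  side (the fold is shared with a neighbouring capsomer; the tile itself
  stays flat there), a **cut** crosses the interior. Each crease is
  further labelled by the number of the hexamer's six *subunit wedges* it
  touches -- the six kites around the tile centre, one per jelly-roll
  tower -- with closed-set touching, so a chord through the centre
  touches all six.
* The hexamer's signature is the multiset of its crease types; $C^h$ is
  the number of distinct signatures across the design.

This reproduces the published calibration set exactly: $C^h = 4$ for
T = 27 (the Sputnik architecture), $C^h \le 2$ for T = 3, 7, 9, 13, 21,
25, and $C^h > 2$ for T = 12, 19, 27. The typing is deliberately
combinatorial rather than metric. A purely metric signature (exact chord
offsets and angles) provably cannot match the published values: the
T = 21 design's two crease geometries (offsets 0.19 and 0.38 lattice
units) must count as one shape class, while the T = 19 design's two
creases -- the same metric situation -- must count as two. The wedge
count captures the difference (both T = 21 creases span three subunits;
the T = 19 creases span four and two) and has a direct physical reading:
it states how many subunits of the trimer a fold line deforms.

```{r complexity}
sapply(list(c(1, 1), c(2, 1), c(3, 1), c(4, 1), c(3, 2), c(3, 3)),
       function(hk) c(T = t_number(hk[1], hk[2]),
                      Ch = hexamer_complexity(hk[1], hk[2])))
```

`allowed_for_trimeric_mcp()` combines the constraints: a design fails with
reason `hexagon-on-two-fold` (trimers cannot straddle a 2-fold),
`complexity` ($C^h > 2$, default bound), or `no-hexamers` (T = 1 has no
hexagonal positions, hence no trimer-built shell at all; without this
clause the "smallest allowed designs" list would begin at T = 1). The
surviving list begins 3, 7, 9, 13, 21, 25.

### Relative dimensions, and a deliberate discrepancy

The atlas reports diameter and volume relative to a reference design
using the only parameter-free model: surface area proportional to $T$
(each design tiles its surface with $60T$ jelly-roll towers of fixed
footprint), hence $D = \sqrt{T/T_{\mathrm{ref}}}$ and $V = D^3$. Under
this law the T = 13 shell has $(13/21)^{3/2} \approx 49\%$ of the T = 21
volume. Published prose for the same comparison gives "approximately
57%", which no stated model in the source reproduces; the atlas
deliberately reports the sqrt-law value and does not tune toward the
printed figure, since guessing the unstated volume model would be a fit
with one free anecdote.

## The pseudo-T = 21 capsid

For $(4, 1)$ the 200 trimer positions decompose into four orbits --
60 + 60 + 20 + 60 -- and the package types them the way the structures
are described: type 1 peripentonal (orbit nearest a 5-fold), type 2
flanking the 2-folds, type 3 exactly on the 3-folds (20 copies, one
monomer per asymmetric unit), type 4 the remainder. Ties in "nearest
axis" cannot occur for (4, 1) but the contract is total: angular
distance with a `1e-9` tolerance, then lowest orbit id. The asymmetric
unit of an odd-$T$ trimer shell carries $(T-1)/2$ MCP monomers, i.e.
$T - 1$ jelly rolls, plus one penton domain: for T = 21, 10 monomers, 20
beta-sandwiches, 21 quasi-equivalent building blocks. Even $T$ is an
error by construction -- the arithmetic shadow of the 2-fold exclusion.

Point models (`build_point_model()`) place pseudo-atoms at capsomer
positions scaled to a physical radius, optionally with a lipid-bilayer
shell of two Fibonacci-sphere leaflets at radius $\pm$ thickness/2
(deterministic, no RNG). They exist for rendering and for exercising the
composite-stitching transforms, not to reproduce capsid faceting: the
model is spherical, so the measured face-to-face/vertex-to-vertex
anisotropy of a real virion is out of scope.

## Sub-particle geometry

Localized reconstruction treats symmetry-related sub-regions of a large
particle as independent single particles. Everything reduces to three
documented conventions:

* **Euler angles** (rot, tilt, psi) are ZYZ intrinsic,
  $A = R_z(\psi) R_y(\theta) R_z(\phi)$, mapping map-frame coordinates to
  the microscope frame (the particle-table dialect).
* **Sub-particle transform**: a site $S\,v$ (symmetry operator $S$, unit
  site vector $v$, radius $r$ in Angstrom) projects at in-plane offset
  $(A S r v)_{x,y}$ (plus the parent origin, converted to pixels), with
  the out-of-plane component recorded as `z_shift`. The sub-particle
  orientation is $A S Q$ where $Q$ = `align_z_to(v)` places the local
  site axis on z. $Q$ is the *minimal* rotation (axis $z \times v$, no
  in-plane twist): aligning the local 3-fold to z fixes only two degrees
  of freedom, and the minimal rotation is the documented resolution of
  the third.
* **Defocus**: positive `z_shift` means farther from the electron source,
  hence more underfocus, hence a larger defocus value; `adjust_defocus()`
  takes a `sign` flag because packages disagree. Over a full orbit the
  adjustments sum to zero (the orbit centroid is the capsid centre) --
  asserted to `1e-6` Angstrom.

Special positions deduplicate by 3D position, not operator index, with
tolerance `1e-6` of the radius: a 6501-particle table yields
6501 x 60 = 390,060 general-trimer sub-particles, 6501 x 20 = 130,020 for
the on-three-fold trimer, 6501 x 12 = 78,012 for the vertex, and a
2351-particle table yields 28,212 vertex sub-particles. C5 symmetry
relaxation (`relax_candidates()`) returns the five orientations related
by the local 5-fold -- in-plane rotations of $72k$ degrees composed on
the map side -- for classification of tilted vertex features; candidate
sets of orientations differing by a C5 step coincide as sets (tested).
Composite stitching inverts the sub-particle transform, replicates each
component over its orbit, and resolves overlaps by mask precedence in
input order: a point of component $i$ is dropped inside the mask sphere
of any later component, emulating the subtract-spike-mask-from-penton-mask
step of composite map assembly. The extract-then-stitch round trip
recovers positions to machine precision (asserted < 1e-6 A).

Everything here is metadata geometry. No image pixels, CTFs, subtraction
of densities, classification or refinement are simulated -- those belong
to the external reconstruction packages.

## Prophage scanning and conservation

The genomic module mirrors how integrated relatives of such phages are
found. Homology hits are *inputs* (a TSV of rep-initiator/MCP hits per
genome); the caller pairs a rep hit with a following MCP hit on the same
strand within `max_gap` (default 10 kb), resolving overlaps greedily by
smallest gap then leftmost -- deterministic and order-independent. Locus
boundaries from hit extents are provisional; finding the two flanking
28-nt dif palindromes refines them to the integration footprint. Lengths
outside the expected 5--10 kb range are flagged, never dropped.

The dif locus is modelled with the canonical bacterial arm--spacer--arm
geometry: an 11-nt XerC arm, 6-nt central hexanucleotide, 11-nt XerD arm.
The 28-mer's partition is configurable because the source material
describes the 28 nt only as "including six extra surrounding
nucleotides". `palindrome_score()` is the fraction of non-spacer
positions whose base complements its mirror partner; it is symmetric
under reverse complement (property-tested exhaustively) and scores
ambiguity codes as mismatches. Site detection demands a palindrome score
of at least 0.9 *and* an upstream/downstream pair with at least 90%
identity; on unmodified random genomes of 15 kb this reports no pair
(tested over 25 seeds), while implanted sites are recovered at their
exact coordinates.

Conservation scoring uses column-wise sum-of-pairs identity with gap
pairs excluded, z-normalised across columns -- the reference method
behind the published per-residue colourings is not reproducible from its
citation, and z-scoring matches the signed score ranges such figures
print. When no column varies, all z-scores are 0 by convention.
`map_conservation_to_model()` writes scores into the B-factor column
(sentinel -99.9 for unmapped residues, declared in a REMARK), and
`logo_matrix()` gives WebLogo-style per-column frequencies and
information content $2 - H$ bits, without small-sample correction.

## Synthetic data: what it does and does not show

All inputs are generated, seeded and bit-reproducible, with ground truth
carried alongside:

* **Particle tables**: orientations uniform over SO(3) via normalised
  quaternions (subgroup-free), defocus uniform over 0.1--2.2 um, pixel
  size 1.24 A -- the published acquisition envelope for this data type.
  Problem sizes 6501 and 2351 particles match the two real data sets
  whose sub-particle counts the analysis reproduces.
* **Genomes**: i.i.d. bases at 30.5% GC (the phage's composition);
  implanted cassettes are 7642 nt (the phage genome length) with
  rep -> MCP -> spike ORFs marked by coordinates and flanked by dif
  copies. ORF content is synthetic sequence: gene calling is out of
  scope, so only coordinates matter. The MCP ORF sits mid-cassette
  (relative 2201--2917), as in the real genome where the MCP is ORF5 of
  15 -- which also keeps both dif sites within the default 5-kb scan
  flank of the provisional locus.
* **Families**: per-site substitution probabilities $2 \cdot
  \mathrm{rate} \cdot v_i$ with $v_i \sim U(0,1)$, optional geometric
  indels with exact alignment bookkeeping. The conservation recovery
  experiment uses 40 family members over 200 columns at mean rate 0.3:
  ranking precision of the sum-of-pairs estimator grows with the number
  of sequence pairs, and 40 sequences (780 pairs) give the Spearman
  $\ge 0.9$ bar comfortable headroom across seeds, where a family of ~20
  would sit on the margin.

Passing these tests shows the *geometry and bookkeeping* are right:
counts, transforms, coordinates, recovery on clean and mildly mutated
data. It does not show performance on real data -- real prophages diverge
by rearrangement and recombination, not i.i.d. substitution; real hit
tables carry noise the synthetic ones lack; and nothing image-domain
(resolutions, B-factors) is simulated at all. The published census of 57
prophages in live databases is likewise out of reach by construction, as
it depends on the database snapshot.

## Known limitations

* $C^h$ is an operationalisation calibrated to the printed values; other
  definitions consistent with those values could differ for large $T$
  not covered by the calibration set.
* The trimer typing scheme is pT = 21-specific by contract.
* Circular genomes are handled by a documented linearisation; a cassette
  spanning the origin is not generated.
* The spherical point model ignores capsid faceting.
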