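---
title: "Methods: probe design, polymer simulation and FISH quantification in oligohops"
author: "oligohops maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probe design, polymer simulation and FISH quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligohops)
```

oligohops implements the computational side of Oligopaint-style FISH: mining
probe sequences from a genome, deriving haplotype-specific (HOP) probe pairs
from a SNP panel, assembling full-length synthesis constructs, simulating
single-molecule localization data on polymer models, and quantifying spot
tables. This vignette documents the models, the defaults and why they were
chosen, the numerical decisions, and what the synthetic fixtures do and do
not establish about real data.

## Coordinates and formats

All intervals are 0-based half-open internally. BED output is 0-based
half-open; VCF positions are converted from 1-based on read and back on
write. FASTA is wrapped at 80 columns; tables are tab-separated with a
header. The VCF dialect consumed is deliberately narrow — CHROM, POS, REF,
ALT and optionally phased GT for haplotype assignment; indels are dropped
with a warning because HOP design is defined over point substitutions only.

## Duplex melting temperature

`tm_nearest_neighbor()` sums unified nearest-neighbour enthalpies and
entropies (the standard unified DNA/DNA parameter set, 1 M NaCl reference
state) over the dinucleotide steps, adds terminal initiation terms and, for
self-complementary sequences, the duplex-symmetry entropy. The temperature
is

$$T_m = \frac{\Delta H^\circ}{\Delta S^\circ + R\,\ln(C_T/x)} - 273.15,$$

with $x = 4$ for non-self-complementary duplexes and $x = 1$ (with $C_T$
the total strand concentration) otherwise. Salt enters entropically,
$\Delta S^\circ{}' = \Delta S^\circ + 0.368\,(N-1)\ln[\mathrm{Na^+}]$, and
formamide linearly at $-0.65\,^\circ$C per percent v/v — the standard
empirical slope for DNA/DNA hybrids. Published probe-design pipelines in
this area do not state their exact Tm model, so the model here is fixed,
documented, and exposed through `thermo_conditions()` rather than
hard-coded: the defaults (1 M Na⁺, 0% formamide, 1 µM total strand) are the
reference state in which the conventional 42-mer acceptance window of
85–99 °C was calibrated; FISH-like conditions are
`thermo_conditions(0.39, 50)` (2× SSC, 50% formamide). The implementation
was checked against an independent nearest-neighbour implementation to
9 decimal places for non-self-complementary probes, and against a literal
hand-summed oracle for a self-complementary one.

## Probe mining

`mine_candidates()` scans every window of length $L$ in the target and
applies, in order: an N-content veto, GC bounds, forbidden motifs
(defaults `GGGG, CCCC, TTTTT, AAAAA` — G-quartets and homopolymer runs
that misbehave in synthesis and hybridization), Tm bounds, and a
genomic-uniqueness screen. Windows that survive are selected greedily
left-to-right: the first passing window is kept, and subsequently every
window at least `min_spacing` starts away from the last kept one, up to
`max_probes_per_target`. Greedy left-to-right selection is deterministic,
order-independent of discovery, and trivially reproducible by a brute-force
oracle, which the test suite exploits: on synthetic contigs the output is
asserted *identical* to exhaustive window filtering with the same
predicates.

The uniqueness screen replaces the BLAST/secondary-structure stages of
full-scale array-design tools with a k-mer criterion: every constituent
k-mer (default $k = 16$) of a probe must occur at most
`uniqueness_max_hits` (default 1) times across both strands of the genome.
A 16-mer that is unique in the double-stranded genome makes the probe's
window necessarily unique as well; the converse is not guaranteed, so this
screen is conservative in what it rejects at desk scale but is *not* a
claim of equivalence to cross-hybridization prediction — no thermodynamic
off-target model is applied. Probes are reported on the plus strand;
reverse-complement emission for strand-specific ssDNA synthesis is an
output option (`write_probes_fasta(reverse_complement = TRUE)`), not a
filter.

## HOP design

For each SNP at position $p$ and probe length $L$, `extract_snp_blocks()`
takes the reference block $[p-(L-1),\,p+L)$ — exactly the windows that can
contain the SNP — clipped at contig edges (flagged). Candidate discovery
runs the full mining filter stack inside each block and requires overlap
with the block's focal SNP; by default one candidate is kept per block.
Requiring the *focal* SNP (rather than any SNP in the block) has a useful
consequence: a SNP is covered by the design exactly when at least one
filter-passing window contains it, so the reported suitability fraction has
a direct brute-force definition that the tests verify. Where one probe
overlaps several SNPs, *all* overlapping haplotype alleles are substituted
into both sequences (`insert_variants()`), and the offsets are reported;
the cognate pair spans identical coordinates by construction, with the
Hamming distance between the two sequences equal to the number of
positions at which the two haplotypes actually differ.

The suitability denominator is every SNP inside the target, including SNPs
lost to clipping, avoidance intervals or filters — the statistic answers
"what fraction of known variants can this chemistry use", not "what
fraction of attempted designs succeeded". On i.i.d. synthetic sequence at
42% GC the fraction lands around 90–97%; real genomes, with repeats and
composition bias, sit far lower (historically ~40% for mouse- and
fly-strain panels).

Interstitial probes run the same filters with hard exclusion of every SNP
position, every HOP footprint and any user-supplied avoidance interval
(e.g. a transcribed region reserved for simultaneous RNA FISH), so they
bind both haplotypes equally and never collide with the allele-specific
set.

## Full-length oligo assembly and secondary-oligo screening

`assemble_full_oligo()` concatenates, 5′→3′: optional secondary/docking
sites, the forward primer, the genomic insert, and the reverse complement
of the reverse primer — the layout in which the synthesized strand is
amplifiable by the primer pair and the non-genomic portion stays
single-stranded after hybridization, available to fluorophore-bearing
secondary oligos. Sites can instead be placed internal to either primer or
split across both ends; the genomic insert always appears exactly once and
is recoverable verbatim (`genomic_insert()`), which the tests assert as a
round-trip invariant.

Secondary oligos are conventionally 32 nt; DNA-PAINT docking strands are
9 nt so the imager duplex is transient at room temperature — the package
treats that duplex length as a sequence-class convention and reports its
predicted equilibrium Tm, not a kinetic model. Orthogonality is screened by
exact longest-common-substring (both strands, binary search over match
lengths) against other sites, probe inserts and the genome, with a default
threshold of 12 nt. For 32-mers this is deliberately conservative and
deterministic; it does not model mismatch-tolerant annealing.
`select_secondaries()` walks a candidate pool greedily, keeping sites whose
perfect-duplex Tm lies in a window and whose LCS against every kept site is
below threshold, and reports the best attainable panel when the request is
infeasible.

## Polymer growth, equilibration and localization simulation

Chains grow on the simple cubic lattice by adding monomers at a uniformly
chosen unoccupied unit-step neighbour of the growing end; after more than
10 consecutive rejections the terminal 10 monomers (or all but the first)
are erased and growth resumes, so growth always terminates. Equilibration
mixes two move types per sweep: $n$ single-monomer displacements to a
neighbouring site, accepted iff the site is free and both adjacent bonds
stay in the squared-length set $\{1,2,3,4,5\}$, plus one pivot move
applying a random non-identity element of the 48-element cubic point group
to the tail beyond a random pivot, accepted iff self-avoiding. The
bond-fluctuation realization here uses single-site monomers with the
fluctuating bond set rather than the classical 2×2×2-occupancy variant;
this keeps excluded volume and bond fluctuation at desk scale, and the
tests verify the physical consequence that matters — equilibrated chains
swell beyond the ideal-walk mean-squared end-to-end distance $N$. The move
kernel is in C++ (Rcpp) and draws from R's RNG, so every run is
reproducible under `set.seed()`.

Localization counts per monomer are integerised exponential draws. A
deterministic `round(Exp(m))` has mean $e^{1/(2m)}\,m\,(1-e^{-1/m})\ne m$
(≈ 1.979 for $m = 2$), a ~1% bias that is material precisely because the
package's own calibration check asks for the mean to be recovered within
Monte-Carlo error; the implementation therefore uses stochastic rounding,
$\lfloor x\rfloor + \mathrm{Bernoulli}(x - \lfloor x\rfloor)$, which is an
integerised exponential with exactly the requested mean. Background events
(default expectation 0.5% of expected foreground — "a small number") are
uniform over the chain's bounding box padded by $3\sigma$; isotropic
Gaussian noise of s.d. $\sigma$ (monomer diameters; default 1) is added to
every event. Subsampling retains exactly `round(f·N)` events, order
preserved. Rendering projects to (x, y) and bins into a histogram (count
conserving) or deposits unit-mass Gaussian kernels; kernel weights are
computed relative to the nearest pixel so that the narrow-kernel limit
reproduces the histogram exactly instead of underflowing.

The fragmentation analysis (component counting of thresholded renderings
via EBImage) uses a straight 600-monomer rod imaged at a mean of 6
localizations per monomer, 1-diameter noise and 2-diameter pixels: 6 per
monomer stands in for activator–reporter-grade density, so that retaining
one third of the events lands at the single-reporter-like ~2 per monomer
and retaining one tenth is sparse. In this regime the component count
increases monotonically as density falls — the quantitative form of
"structures fall apart at low localization density". At much lower full
densities the relation inverts (few occupied pixels means few components),
which is why the fixture pins the high-density condition.

## Quantification rules

Exactly as conventionally scored: two signals in the same nucleus and
channel merge when their *edge-to-edge* distance (centre distance minus
both radii) is strictly under 1 µm, with single-linkage transitive closure
(a chain of close signals is one focus) — the closure choice makes merging
order-independent and matches the "considered a single focus" reading for
chains. Focus centroids are unweighted member means; the effective radius
is that of the smallest centroid-centred sphere enclosing all members.
Chromatic offsets between channels are constant translation vectors
supplied by the user (measured instrumentally upstream; a typical red/green
offset is ~177 nm laterally) and are tracked so a double application
errors. Co-localization uses strict thresholds, lateral
$\sqrt{dx^2+dy^2} < 250$ nm *and* axial $|dz| < 600$ nm; pairing uses an
inclusive edge-to-edge $\le 0.8$ µm — the strict/inclusive asymmetry
follows the printed conventions. The headline co-localization percentage is
directional, and the two published phrasings disagree on the direction, so
`colocalize()` takes an explicit `direction` argument with
secondary-in-primary as the default reading. Nuclei lacking signal in
either channel are excluded from concordance tables and counted
separately.

The two-tailed Fisher test is computed in-package (hypergeometric point
probabilities with fixed margins; two-tailed mass is the sum over tables
whose probability is at most that of the observed table, ties at a
relative tolerance of 1e-7; odds ratio is the sample ad/bc with 0/∞
conventions) and is verified in the tests against full enumeration for
every 2×2 table with $n \le 40$ and against the stock R implementation —
the package value is never delegated to either.

## Synthetic fixtures: what they emulate, and what they do not

`synth_genome()` draws i.i.d. sequence at a requested GC (default 42%) and
plants SNPs uniformly without replacement at a requested density (default
7/kb, a fly-strain-pair-like figure; mouse strain pairs run 2–3/kb), with
ref alleles consistent with the emitted FASTA. It does **not** emulate
repeats, segmental duplications, composition domains or clustered
variation — so suitability fractions and probe yields on these fixtures are
upper bounds, and passing oracle-equivalence tests establishes correctness
of the *filtering logic*, not performance on a real genome.
`synth_spot_field()` plants per-nucleus pairing states (default probability
0.32 across 101 nuclei, the scale of a classic embryo-pairing experiment),
separates paired signals by half-normal per-axis offsets (default s.d.
200 nm, comfortably inside the 0.8 µm call) and unpaired signals by
2.5–5 µm, with optional per-channel dropout and a simulated chromatic
offset. It does not simulate segmentation errors, z-anisotropy or
background foci; ground-truth recovery tests therefore validate the
scoring rules, not detection.

## Problem sizes and runtime

The shipped tests run oracle-equivalence on 10–20 kb contigs (where
exhaustive filtering is exact and fast), the Fisher enumeration over all
tables to $n = 40$, simulator calibration over 50 replicates of 1,500
monomers, and ground-truth recovery over 2,000 nuclei; the full suite
completes in under two minutes on one CPU. These sizes were chosen so that
every check is exact or has narrow Monte-Carlo error, while remaining
desk-scale; nothing in the methods limits them — the same code mines
multi-megabase targets in minutes.

## Known limitations

* No cross-hybridization thermodynamics, secondary-structure or LNA
  chemistry modelling; the k-mer screen and LCS screen are stated,
  conservative substitutes.
* Tm conditions for probe acceptance are configurable but a single global
  pair of bounds; no per-probe condition optimisation.
* The polymer model is a lattice homopolymer with no confinement,
  chromatin-specific contact energies, or photophysics beyond the
  exponential cycle count.
* Quantification starts from spot/localization tables; detection,
  segmentation and drift correction are upstream of this package.
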