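---
title: "Methods: comparative mitogenomics of anomuran crustaceans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative mitogenomics of anomuran crustaceans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anomito)
```

# What the package computes

`anomito` is a pipeline for comparative analysis of anomuran (hermit crab,
king crab, squat lobster) mitochondrial genomes. Its stages are:

1. **Ingestion** (`read_genbank`, `read_fasta`): annotated mitogenomes are
   read from GenBank flat files; heterogeneous gene labels are mapped onto
   a closed 38-symbol vocabulary (13 protein-coding genes, 22 tRNAs with
   `trnL1/trnL2` and `trnS1/trnS2` disambiguated by anticodon, two rRNAs,
   and `CR` for the control region).
2. **Composition** (`composition`, `at_skew`, `gc_skew`, `codon_usage`):
   per-strand base composition, AT/GC strand-asymmetry skews
   (`(A-T)/(A+T)` and `(G-C)/(G+C)`), and codon usage with RSCU.
3. **Gene order** (`canonicalize`, `partition_types`, `diff_vs_reference`,
   `breakpoint_distance`): canonical signed circular permutations,
   arrangement typing, and rearrangement diffs against the pancrustacean
   ground pattern.
4. **Selection** (`codon_align`, `kaks_ng86`, `sliding_window`,
   `depth_pair_report`): NG86 Ka/Ks estimation for depth-matched species
   pairs, per gene and in 52-codon sliding windows, with Fisher exact
   significance.
5. **Control region** (`locate_control_region`, `find_tandem_repeats`,
   `find_ssrs`, `find_inverted_repeats`, `annotate_motifs`, `fold_mfe`):
   tandem repeats, microsatellites, hairpins, motif blocks, and
   minimum-free-energy secondary structure with its folding free energy
   (dG, kcal/mol).
6. **Depth association** (`assign_depth_category`, `dg_depth_trend`,
   `carcinization_contrast`): family-wise Spearman association between
   control-region dG and habitat depth, contrasting carcinized
   (crab-like) and non-carcinized lineages.

A deterministic synthetic-data generator (`generate_genome`,
`generate_control_region`, `evolve_codon_pair`) provides inputs with
recorded ground truth; every stage is validated against it or against an
independent brute-force reference.

# Conventions

Coordinates are 1-based inclusive on the deposited plus strand (GenBank
convention); a feature spanning the circular origin is stored with
`start > end` and a wrap flag. The deposited plus strand is treated as the
heavy strand for skew bookkeeping, overridable per record: published
reports do not always state the heavy/light mapping, so the package emits
pure per-strand skews *and* a "mixed" report row (heavy-strand AT skew
with light-strand GC skew). The mixed convention is the only one under
which the published skew pairs for the three newly sequenced anomurans are
arithmetically reproducible from their published strand compositions, so
it is what `skew_report` labels `mixed`; both pure rows always accompany
it.

Report rounding is half-away-from-zero (`round_half_away`): 1 decimal for
percentages, 3 for skews, matching the precision of published tables.
Translation uses the invertebrate mitochondrial genetic code (NCBI
table 5) throughout; incomplete terminal stops (T/TA) are trimmed, not
padded, when CDSs are extracted in frame.

# Control-region location

The control region is located as the single longest unannotated circular
gap; an explicit CR/D-loop annotation takes precedence. Genomes whose
largest gap is under 50 bp are flagged `"too compact"` rather than given a
spurious region - published comparative tables mark several pagurid
records this way, and the shortest control region reported as real is
63 bp, so 50 bp keeps every reported region while rejecting ordinary
intergenic spacers.

# Gene-order analysis

A gene order is a circular sequence of signed symbols; canonical form
starts at `+cox1`, reflecting (reversing with sign flips) first if `cox1`
lies on the minus strand. Arrangement types are equivalence classes under
exact equality of canonical orders, over all 37 genes, excluding CR
placement, with strand significant; duplicated genes are expanded to
`gene_copy2, ...` so exact-equality semantics survive lithodid tRNA
duplications. Type identifiers are assigned in first-seen order after
sorting by accession, for determinism.

Breakpoint distance counts signed circular adjacencies of one order absent
from the other, identifying an adjacency `(a, b)` with its opposite-strand
reading `(-b, -a)`; it satisfies identity and symmetry but the triangle
inequality is not asserted. `diff_vs_reference` reports a shared gene as
*translocated* when both of its reference adjacencies are broken **and**
its unsigned neighbour set changed, and as *inverted* when the
neighbourhood is conserved but its own sign flipped. The additional
neighbour-set condition matters: when two genes swap around a third, the
middle gene keeps its neighbour set (only reversed) and is not itself
reported as moved.

Two reference patterns ship: `canonical37`, the complete 37-gene
pancrustacean ground pattern with strands, and `paper`, the 32-gene anchor
string as commonly printed in the comparative literature (it omits trnG,
trnA, trnV, rrnL and rrnS and orders nad3 ahead of the trnM-trnI-nad2
block). The printed string carries no strand information, so strands are
assigned from the canonical pattern. `canonical37` is the default
reference; the printed string remains selectable because it is the anchor
many published comparisons quote.

# Ka/Ks estimation

The estimator is NG86 counting with equal pathway weighting and a
Jukes-Cantor correction:

* Site counting partitions each codon position by its mutational fates
  under code 5; changes that create a stop codon are excluded from both
  numerator and denominator, so `L_A + L_S = 3 x` (unmasked codons)
  exactly. Sites are averaged over the two sequences.
* Multi-nucleotide codon differences are averaged over all minimal
  substitution pathways; pathways through stop codons are excluded unless
  every pathway is blocked.
* `Ka = JC(S_A / L_A)`, `Ks = JC(S_S / L_S)` with
  `JC(p) = -3/4 log(1 - 4p/3)`; a proportion at or above 0.75 is a
  saturation error.
* `omega = Ka/Ks`, reported as 0 when `Ka = 0, Ks > 0` (matching the shape
  of published pairwise tables) and flagged undefined when `Ks = 0`.

Published anomuran pairwise tables were produced with a gamma-rate
estimator from a different method family; its rate-variation machinery is
out of scope here, so exact published Ka/Ks values are treated as
qualitative anchors only (their estimator-robust features - omega below 1
throughout, zero-Ka rows - are what the validation asserts). The Fisher
exact test follows the convention of pairwise Ka/Ks tools: a 2x2 table of
substituted versus non-substituted sites with rows
nonsynonymous/synonymous, real-valued counts rounded half away from zero,
two-sided p.

Alignment is translation-guided: amino-acid global alignment (BLOSUM62,
affine gaps, gap opening 10 / extension 0.5) back-threaded onto codons;
columns containing a gap or stop are masked but counted. Sliding windows
are 52 codons at a step of 12 - window units in the source literature are
unitless, and codon windows keep reading frames intact; a trailing partial
window is dropped, and windows with `Ks = 0` are flagged rather than
dropped.

# Control-region characterization

**Tandem repeats.** The detector follows the Tandem Repeats Finder recipe
at its documented default weights (match +2, mismatch -7): recurring
k-mers at constant spacing seed candidate periods, a rolling consensus is
voted per phase, and the reported array is the maximal-scoring contiguous
segment; copy number is span/period to one decimal. Two deliberate
departures: indels inside arrays are not modelled (the generator plants
point mutations only, and anomuran control-region repeats are
substitution-dominated at the ~5% divergence scale), and the default
minimum score is 20 rather than the upstream tool's 50, because a perfect
`(AT)x6` array - the kind of short repeat the comparative tables report -
scores only 24 under these weights.

**Microsatellites** are maximal perfect runs of a 1-6 bp primitive unit,
left-greedy, with per-unit-length copy thresholds (12, 6, 4, 3, 3, 3).
**Inverted repeats** use seed-and-extend comparison against the reverse
complement under einverted-style match/mismatch scores (+3/-4, gaps not
modelled); the default reporting threshold is a score of 30 - exactly a
perfect arm at the 10 bp minimum arm length - rather than the upstream
default of 50, which would silently reject the 12-15 bp hairpin arms the
figures of comparative studies display. **Motif blocks** are deterministic
patterns: GA blocks (>= 6 nt of G/A with >= 2 G), poly-T (>= 5 T), and
`[TA(A)]n` (>= 3 TA/TAA units), with GA blocks subtyped 5'/3' relative to
the main tandem repeat. The thresholds are config defaults chosen to
reproduce the block counts visible in published control-region figures;
they are not published values.

# Secondary-structure folding

`fold_mfe` implements Zuker-style dynamic programming under a loop-based
nearest-neighbour model: stacking energies by pair type, tabulated
hairpin/bulge/internal penalties (internal and bulge loops capped at 30
unpaired nt - the standard MAXLOOP convention, which the model treats as a
hard validity rule so the DP and the enumeration reference share one
definition), affine multibranch loops, free exterior bases, minimum
hairpin loop 3, no dangles or terminal-pair corrections. DNA input is read
as RNA (T as U) because the published procedure folded control-region DNA
with an RNA-folding server; reproducing that procedure, not thermodynamic
realism for DNA, is the goal. Parameters are packaged as dH plus dG at
37 degC for stacks (loops treated as purely entropic) and rescaled to the
working temperature via `dG(T) = dH - T dS`; the default 27 degC matches
the published setting. The table is Turner-style but not any server's
exact set, so published dG ranges are qualitative anchors; the
quantitative correctness claim is oracle equivalence: on random sequences
up to 30 nt the DP equals exhaustive enumeration of every valid structure
under the same table to below 1e-6 kcal/mol (500 sequences in the
acceptance run; about 5 million structures are evaluated).

Up to 20 suboptimal structures within 1 kcal/mol are reported by refolding
with one MFE pair forbidden per round, candidates ordered helix-closing
pairs first and attempts capped at twice the requested count; this is a
documented heuristic, not the complete suboptimal enumeration of the
Wuchty algorithm, and it guarantees only that every reported structure is
valid, distinct and within the band. GU wobble pairs are allowed by
default; note that strand symmetry (equal dG after reverse
complementation) holds only for the Watson-Crick subset, since a GU pair
complements to an unpairable A:C - the symmetry test therefore runs with
`allow_wobble = FALSE`.

A tRNA-scale fold is called a cloverleaf iff the MFE structure has an
acceptor stem of >= 4 consecutive pairs from the outermost pair and
exactly three hairpin loops; anything else (including the open chain) is
atypical.

# Depth association

Habitat data are packaged as a per-species table transcribed from the
comparative literature: control-region length (or "Too compact"), AT
content, repeat summaries, dG ranges, depth ranges and climate, for 49
species (42 anomurans plus brachyuran and other outgroups). Since only
ranges are published, per-species summaries are range midpoints for both
depth and dG. The association is the Spearman rank correlation per family,
with a permutation p-value (>= 10,000 shuffles under a fixed seed, exactly
reproducible). Sign convention: "dG decreases with depth" means
`rho(depth, dG) < 0`, i.e. more stable folds in deeper species; where the
source's prose and its own parenthetical disagree about this sign, the
parenthetical and the table arithmetic are followed.

Exclusions: species with no numeric dG ("Too compact"), fully terrestrial
rows (no depth gradient), and hydrothermal-vent taxa (Munidopsidae), whose
dG reflects vent conditions rather than depth and which are counted
separately. The default of at least 4 usable records per family is
exposed as `min_n`; the Diogenidae direction check requires `min_n = 3`
because only three usable rows exist, and a permutation p on three points
is reported but not meaningful. Carcinized families default to
{Lithodidae, Porcellanidae, Lomisidae} - the first two on the explicit
authority of the comparative literature, Lomisidae as a further
convergently carcinized lineage - and the set is an editable argument.
The contrast output is descriptive (modal direction per group and a
sign-concordance fraction); no phylogenetic correction is attempted, so
the association must not be read causally.

# The synthetic-data generator

The generator emulates the study conditions: circular 14-18 kb genomes
with 37 genes plus one control region; PCGs as random ORFs at realistic
per-gene lengths (ATG start, TAA stop, no internal stops); tRNAs of
60-75 nt; strand-asymmetric target composition defaulting to the
published heavy-strand values (A 31.7%, C 9.8%, G 16.7%, T 41.8%);
control regions of 1300 bp at AT-rich composition with a planted
47 bp x 3.6 tandem repeat mutated at 5% per base per copy, GA/poly-T/TAA
blocks and hairpin stems at recorded coordinates; and homologous codon
pairs evolved by a continuous-time process (transition bias `kappa`,
nonsynonymous acceptance `omega`, stop-generating changes rejected,
branch lengths scaled so the expected synonymous divergence equals `t`).
All outputs are pure functions of their spec including the integer seed
(R's Mersenne-Twister, seeded locally with the caller's RNG state
restored).

Two generator choices deserve emphasis. First, `kappa` defaults to 1:
the codon harness exists to validate an estimator whose site counting
assumes equal rates, so the calibration runs under the estimator's own
model; raising `kappa` is the intended sensitivity analysis and will show
the classical bias of equal-rate counting. Second, synthetic tRNA genes
are plain random segments - they need not fold into cloverleaves - and a
separate helper (`synthetic_trna`) emits designed stem-loop sequences for
folding tests, keeping order-level tests independent of folding tests.

What the generator does **not** emulate: indels in coding sequences or
repeat arrays, codon-frequency bias fitted to real mitogenomes,
among-site rate variation, gene overlap, and sequencing error. Passing
the planted-truth recoveries therefore demonstrates algorithmic
correctness under the stated model, not robustness to every feature of
real annotation pipelines.

# Validation problem sizes

The shipped tests and the acceptance script use: 500 random sequences of
10-30 nt for the folding oracle; all alignments of up to three codons
over a fixed four-codon panel (with invariant padding) for the pathway
oracle; 100 replicate 500-codon pairs at `omega = 0.2, t = 0.3` for
parameter recovery (mean absolute bias below 0.05); 50 seeded 1300 bp
backgrounds for the 47 bp x 3.6 repeat recovery (period within 1 bp and
copy number within 0.3 in at least 90%); and 200 random signed circular
permutations of up to 15 genes for the breakpoint/typing oracle. These
sizes were chosen as the smallest at which the stochastic checks are
stable from run to run.

# Known limitations

* No de-novo annotation, assembly, or remote fetching: accession
  identifiers resolve only to local files.
* The NG86-family estimator deliberately omits gamma rate variation;
  published values from that family of estimators are matched only in
  their robust features.
* Folding ignores dangles, coaxial stacking, terminal-pair penalties and
  pseudoknots, and does not compute the partition function.
* The repeat finder does not model indels inside arrays.
* The depth association is descriptive; no phylogenetically independent
  contrasts are computed (no tree input is in scope).
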