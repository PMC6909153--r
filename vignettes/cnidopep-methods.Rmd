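---
title: "Annotating multi-copy neuropeptide preprohormones: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating multi-copy neuropeptide preprohormones: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnidopep)
```

## The biological model

Cnidarian neuropeptide genes encode *preprohormones*: a signal peptide, an
often acidic pro-region, and then a tandem array of near-identical peptide
*cassettes* — from three up to thirty-two copies on one precursor —
separated by short spacers. Each cassette ends in a classical
prohormone-convertase processing site: a mono-, di- or tribasic K/R tract
(R, RR, KR, RRR, RKR, RKK, ...), frequently preceded by a glycine. The
convertase cleaves C-terminally of the basic tract; carboxypeptidase
activity removes the basic residues; and when a G immediately precedes the
tract it is converted into a C-terminal amide group on the mature peptide
("...GRFamide"). N-terminal maturation is performed by an unspecific
aminopeptidase that removes preferred residues (E, D, S, T, N, G, A, L, V,
Y, F) one at a time and stops at:

* **Q** — cyclised to an N-terminal pyroglutamate (written `pQ`), or
* **P** in position 1 or 2 — the X–P bond is an imide and resists
  hydrolysis.

This chemistry is what `cnidopep` encodes, and it is strong enough to pin
down the mature products of a precursor from sequence alone: peptides such
as `RPRSamide`, `pQWLRGRFamide` or `pQPPGVW` are *fixed points* of the
trimming rules, and the package's regression tests assert this for all 22
published mature peptides shipped in `published_peptides`.

## The detection rule

A protein is screened (`screen_protein()`) by:

1. locating processing sites (`find_processing_sites()`): maximal-munch
   K/R tracts of length 1–3, scanned left to right, with `g_preceded`
   recorded. By default a *monobasic* tract only counts with a G donor
   (`GR`/`GK`), while multibasic tracts count regardless. Bare monobasic
   R/K occurs so often in ordinary proteins (and inside peptides such as
   RPRSamide itself) that admitting it would shred true cassettes and
   flood the screen; the permissive variant remains available via
   `site_grammar(mono_R_requires_G = FALSE)`.
2. slicing candidate cassettes (`extract_candidates()`): the raw segment
   between consecutive sites (ending before the donor G), kept if 3–30
   residues long. The bounds bracket the published peptides (shortest
   mature peptide 4 residues, longest families well under 15) with head
   room for spacers.
3. clustering candidates (`cluster_candidates()`): single-linkage under
   *right-anchored* identity — matches after right-aligning two segments,
   divided by the shorter length, with `X` matching nothing. The
   C-terminal anchor reflects the biology: C-termini are conserved,
   N-termini variable. The similarity threshold (0.5) is a declared free
   parameter; the sources do not quantify "similar".

A protein is a **hit** when some cluster holds at least `min_copies = 3`
members ("at least three similar peptide sequences"). A site-count-only
mode (`mode = "site_count"`) implements the weaker pre-curation reading —
at least three processing sites — since the original description supports
both readings.

## Curation

The published screen was followed by manual curation on three criteria:
signal peptide, three or more potential neuropeptides, and overall
precursor architecture. `classify()` codifies this as:

* **accepted** — detector hit *and* signal peptide present;
* **review** — hit without a signal peptide (assembled transcripts are
  often 5'-truncated, so these are genuine candidates, not errors);
* **rejected** — no hit.

Signal peptides are called by a transparent three-criterion heuristic
(`predict_signal_peptide()`): a ≥7-residue hydrophobic window with mean
Kyte–Doolittle hydropathy ≥ 1.6 inside the first 36 residues, a
non-negatively charged n-region before it, and a small-residue (A, G, S,
C, T, V) −3/−1 signal-peptidase motif within 8 residues after it. This is
*not* a neural-network predictor and is not meant to compete with one;
`read_signal_calls()` injects externally computed calls bit-exactly when
higher fidelity matters. The heuristic's role here is to reproduce the
curation logic on synthetic data without any external tool.

The "overall structure" criterion is not operationalised anywhere in the
sources; the cluster span over protein length is reported
(`cluster_coverage`) but never gates the decision.

## Maturation

`cleave()` returns the raw inter-site segments with their amidation state.
`mature_all()` then strips N-terminal K/R left against the upstream tract
(convertase remnants — K and R are never aminopeptidase substrates, which
is exactly why RPRSamide and KPRSamide survive) and applies
`trim_n_terminus()` with the rule order: Q-stop, P-at-1, P-at-2, trim
preferred residue, otherwise stop "blocked". The order is forced by the
published peptides themselves: `LPRSamide` requires the X–P rule to beat
the trimmable-L rule. Products shorter than 3 residues are rejected.
Trimming is idempotent, and a `trim_blocked` flag marks products whose
printed form could only be reached through a residue outside the
preferred set — the sources are silent on those cases, so the package
reports rather than forces them.

Copy counts are multisets of display strings, so amidated and
non-amidated variants of one core (e.g. `pQPPGVWamide` / `pQPPGVW`) are
counted separately, as in the published tables.

## Families and consensus

`group_families()` buckets mature peptides by their C-terminal anchor
(last 3 residues of the core plus amidation state), merges non-amidated
variants with an identical amidated core, and then merges buckets
agglomeratively under **complete linkage**: two buckets join only when
*every* cross pair of cores reaches right-anchored identity 0.5,
most-similar pairs first with lexicographic tie-breaks. Complete linkage
is a deliberate choice: at a 0.5 threshold over 4-residue cores, single
linkage chains almost any pair of short anchors (RPRS matches RGRF at
2/4) and would collapse the two ubiquitous families (X1PRX2amide and
GRFamide) that the published grouping keeps separate.

Where precursor architecture is available, a per-peptide `arch` label
(`precursor_architecture()`: exclusively monobasic vs predominantly
dibasic site usage) blocks merges between architecturally incompatible
buckets. This is what keeps `GPRRamide` — whose precursors use only
single-basic sites and DEIT-type spacers — out of the X1PRX2amide family
despite 50% anchor identity.

`consensus()` right-aligns the members and emits unanimity residues or
numbered wildcards with their observed residue sets
(e.g. `X1PRX2amide` with `X2 ∈ {S, A, G}`); `presence_matrix()` builds the
family × class overview with breadth and class-specificity flags;
`cystine_loop_size()` annotates presumed cystine bridges (the cyclic
FRamide peptides form six-rings) without modelling oxidation chemistry.

Known limitation: on sequence identity alone `pQLRPamide` and
`pQLRGamide` merge (0.75 identity); the published tables separate them
only by which classes they occur in. Class-aware splitting is out of
scope.

## Homology search

`local_align()` is a deterministic affine-gap Smith–Waterman (BLOSUM62,
gap open 11, extend 1, a gap of length L costing open + L·extend),
delegated to `Biostrings::pairwiseAlignment` and cross-checked in the
tests against an independently coded dynamic program.
`search_translated()` six-frame-translates a nucleotide dataset and
reports hits above a raw score threshold (default 60). No E-value
statistics are attempted — at desk scale a raw score plus identity is
sufficient for cross-annotation, and the hit lists make no claim of
matching any particular heuristic search tool.

## Alignment, distances and trees

`progressive_align()` is a small, fully deterministic progressive
aligner: 3-mer distances feed a UPGMA guide tree, and profiles are merged
by global profile–profile alignment with affine gaps (open 10, extend 1),
ties resolved diagonal-first so gaps land leftmost. Pre-aligned input is
accepted verbatim. `p_distance()` implements the proportion of differing
sites with pairwise (default) or complete deletion; a pair with no
comparable sites is an error naming the pair.

`parsimony_score()` is a bitmask Fitch dynamic program over compressed
alignment columns; gaps are a 21st character state by default
(`gap_mode = "missing"` treats them as fully ambiguous), and `X` is always
ambiguous. `best_tree()` searches topologies:

* **exhaustively** up to 8 taxa (3, 15, 105, 945, 10395 unrooted
  topologies at 4–8 taxa), taking the minimum with ties broken by the
  lexicographically smallest canonical Newick string;
* by **seeded iterated local search** beyond that: NJ plus random starting
  topologies, NNI steepest descent with a bounded number of sideways
  (equal-score) moves, and perturb-and-reclimb kicks. Parsimony
  landscapes are plateau-rich; plain NNI descent demonstrably stalls one
  step short of optima that plateau traversal reaches, and randomised
  tie-breaking keeps restarts from collapsing onto a single deterministic
  walk. The whole search is reproducible from its seed.

Because the published tree protocol conflates a parsimony criterion with
p-distances and its software settings are unrecoverable, the package
reports **both** a maximum-parsimony tree and an NJ-on-p-distance tree;
the scientific claim being checked — the class topology
(((Cubozoa, Scyphozoa), Staurozoa), Octocorallia) — must hold under both.
Trees are rooted on the octocoral outgroup when requested, matching how
the published figures are drawn. `canonical_newick()` serialises
topologies byte-stably (rooted at the smallest tip, children ordered by
smallest descendant label).

## The synthetic-data generator

`generate_precursor()` builds precursors the way the studied genes are
organised: signal peptide, acidic pro-region closed by a `GKR` site, then
spacer + core + site cassettes, and a C-terminal tail. Defaults are the
study conditions, fixed once:

* copy numbers 3–32; default site `GKR`, with per-family weights over the
  classical inventory;
* spacers of 1–4 residues from the trimmable set plus K — so the
  generator exercises the trimming rules nontrivially — constrained to
  contain no processing sites of their own: the final residue avoids G
  and K (which would graft onto the next cassette's grammar), and a K is
  never placed directly after a K or a G (which would create a dibasic
  tract or a donor-bearing monobasic site inside the spacer);
* a pro-region of 31–40 residues, which keeps the signal-bearing leading
  segment outside the 3–30-residue candidate window and precursors above
  the 60-residue ORF floor even at three copies;
* per-copy substitution noise 0 by default ("similar or identical"
  copies), configurable.

Ground-truth mature displays are computed by the same remnant-strip +
trim chemistry the pipeline applies, so truth and recovery agree by
construction and copy-count comparisons are exact, not approximate.
`generate_transcriptome()` back-translates with uniform synonymous codon
choice, adds i.i.d. background-frequency decoy proteins and UTR padding
(the 5' UTR carries an in-frame stop so stop-to-stop ORFs recover each
protein exactly), and shuffles record order. `diverge()` evolves one
ancestral precursor along the fixed four-class topology with fast spacer
and slow core substitution (C-terminal anchors held), so the true history
of the resulting datasets is the class tree.

What the generator does **not** emulate: realistic codon usage, indels,
assembly errors, genuinely novel peptide families, or cores that embed
processing motifs. That last point matters: GRFamide cores themselves
contain `G+R`, so a fully automated segmentation splits them — the
published analysis absorbed this with manual curation, and the package
surfaces such proteins as hits whose boundaries need review rather than
pretending to resolve them. Passing the synthetic suite therefore shows
the rules are implemented faithfully under the stated precursor
architecture; it does not show that recall on real, messy assemblies
matches the published study.

A related honest property of the screen: about 0.25–0.5% of i.i.d. decoy
proteins contain three mutually similar short segments before basic
tracts and fire the raw detector. These decoys lack signal peptides and
are never *accepted*; recovery statistics are therefore measured at the
annotation level, exactly where the published workflow placed its manual
curation.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run, per seed: a 206-record
transcriptome (200 decoys + 6 precursors) end to end; 50 random 7-taxon
alignments comparing hill-climb to exhaustive parsimony; 8 Fitch columns
against brute-force state enumeration on 6-leaf trees; 20 NJ
reconstructions from additive matrices; and a 4-taxon class-divergence
recovery under both tree methods. These sizes were chosen to pin the
properties down while keeping a full run in the low minutes on one core.

Other numeric choices: identity and merge thresholds 0.5 (declared free
parameters); signal-peptide hydropathy cutoff 1.6 on the Kyte–Doolittle
scale with a 7-residue window (classical h-region values); local
alignment report threshold 60 raw BLOSUM62 units; NNI sideways budget 15
and 3 perturbation kicks per restart; all RNG consumption wrapped so the
caller's RNG state is never disturbed.
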