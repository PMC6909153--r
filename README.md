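# cnidopep

Annotation of multi-copy neuropeptide preprohormones in cnidarian
genomes and transcriptomes.

Cnidarian nervous systems are strongly peptidergic, and their
neuropeptide genes have a distinctive architecture: a signal peptide
followed by three to thirty-two near-identical peptide *cassettes*,
each flanked by classical prohormone-convertase processing sites
(G-preceded and plain mono-/di-/tribasic K/R tracts). `cnidopep` is an R
package for people who want to find these genes in translated assemblies
and predict their mature products. It implements, end to end:

* six-frame stop-to-stop ORF translation of nucleotide FASTA;
* a detector for tandem arrays of similar peptide cassettes ("at least
  three similar peptide sequences followed by classical processing
  sites"), with a reproducible accept/review/reject curation stage
  (signal-peptide heuristic plus an external-call hook);
* explicit maturation chemistry — cleavage C-terminal of basic tracts,
  glycine-donated C-terminal amidation, and N-terminal aminopeptidase
  trimming over the preferred residues E, D, S, T, N, G, A, L, V, Y, F,
  stopping at Q (→ N-terminal pyroglutamate, `pQ`) and at P/X-P;
* cross-dataset peptide families with C-terminally anchored consensus
  motifs (e.g. `X1PRX2amide` with `X2 ∈ {S, A, G}`), a family × class
  presence/absence overview, and cystine-loop annotation for the cyclic
  FRamide peptides;
* a deterministic local-alignment search across translated datasets;
* preprohormone phylogenies: a progressive aligner, p-distance, Fitch
  maximum parsimony (exhaustive to 8 taxa, seeded iterated local search
  beyond) and neighbor joining, with canonical Newick output;
* a ground-truthed synthetic-data generator, so every stage is testable
  without downloading any assembly.

## Worked example

Simulate a staurozoan-style precursor carrying 11 copies of an RPRSamide
cassette, then annotate it:

```r
library(cnidopep)

spec <- precursor_spec("demo_precursor", core = "RPRS", n_copies = 11,
                       class_label = "Staurozoa",
                       spacer_pool = c("D", "V", "F", "A"))
sim <- generate_precursor(spec, seed = 42)

scr <- screen_protein(sim$record)
scr
#> <cnido_screen> demo_precursor: 12 processing site(s), 1 cluster(s), HIT
#>   cluster of 11 (medoid TRPRS, mean identity 0.764)

sig <- predict_signal_peptide(sim$record)
sig
#> <signal_call> present=TRUE cleavage_pos=13 score=0.87 (heuristic)

ann <- mature_all(classify(scr, sig))
ann
#> <cnido_annotation> demo_precursor: ACCEPTED (signal=TRUE, hit=TRUE)
#>   mature peptides:
#>     RPRSamide x11
```

The detector found one cluster of 11 similar cassettes (12 sites: the
pro-region boundary plus one per cassette); the signal-peptide heuristic
fired; and maturation — cleavage after each basic tract, removal of the
glycine amide donor, N-terminal trimming stopping at the X-P imide —
yields exactly 11 copies of `RPRSamide`, the generator's ground truth.

Family grouping reproduces the cross-class consensus of the ubiquitous
XPRXamide peptides:

```r
fams <- group_families(c("RPRSamide", "LPRSamide", "RPRAamide",
                         "GPRGamide", "KPRSamide"))
fams[[1]]$consensus
#> X1PRX2amide
#>   X1 in {G,K,L,R}
#>   X2 in {A,G,S}
```

For whole datasets, `pipeline_config()` + `run_pipeline()` drive
translate → scan → curate → mature → families (→ trees) with a run log
and TSV intermediates; `benchmark()` compares observed copy counts
against the published per-precursor counts for any assemblies you have
fetched yourself (`published_copy_counts()` ships the expected table;
fetching is deliberately manual so the package stays network-free). A
thin command-line wrapper lives at `inst/scripts/cnidopep`.

See the methods vignette (`vignettes/cnidopep-methods.Rmd`) for the
processing model, parameter defaults and design rationale.

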