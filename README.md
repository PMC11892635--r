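# bicistroscan

Sequence-level analysis of **bicistronic loci** in green algae — nuclear
genes whose mature mRNAs carry two independently translated ORFs, each
with its own start and stop codon, separated by a short inter-ORF
spacer. The package is built for the **leaky ribosomal scanning** model:
a suboptimal Kozak-like context at the ORF1 start codon lets a fraction
of scanning 43S preinitiation complexes pass ORF1 and initiate at ORF2,
so downstream translation is tunable through the upstream initiation
context. It is aimed at people curating polycistronic annotations from
long-read transcriptomes and at synthetic biologists designing
bicistronic expression constructs.

## What it computes

* **Detection** — classify loci from genome FASTA + GFF3 (one CDS group
  per ORF, grouped by CDS `ID`) as monocistronic / exclusively
  bicistronic / mixed; extract 5' UTR, ORF1, inter-ORF, ORF2, 3' UTR
  region sequences; uORF scans and structural length statistics.
* **Kozak-like scoring** — train a 13-nt position weight matrix
  (−5..+8, AUG at +1..+3) on half of the monocistronic genes; score any
  site as the mean sequence-logo letter height over the 10 flanking
  positions,

  `R_i = 2 + Σ_b p_i(b) log2 p_i(b)`,  `score(x) = mean_i p_i(x_i) · R_i  ∈ [0, 2] bits`,

  and report per-locus ORF1:ORF2 score ratios and all "internal" AUG
  contexts upstream of ORF2.
* **AUG depletion** — observed vs GC-adjusted expected counts of AUG
  3-mers per region class, `E = (L − 2) · pA · pT · pG`, with o/e ratios
  and class medians.
* **Conservation** — reciprocal-best-hit orthologs from tabular
  (outfmt-6) protein hits and colinearity calls (same strand, adjacent,
  bounded separation) in target genomes, tiered by Iso-Seq/EST support.
* **Expression** — ORF1–ORF2 correlations of log10 RNA-Seq/Ribo-Seq
  abundances, ORF1>ORF2 occupancy fractions, and the (negative, under
  leaky scanning) relation between upstream Kozak strength and relative
  ORF2 footprint density.
* **Construct audit** — the design rules (short 5' UTR; suboptimal ORF1
  context; no upstream AUG besides the ORF1 start; strong ORF2 context)
  applied as checks, plus exhaustive Kozak tuning and AUG-removal edit
  suggestions.
* **Synthetic data** — a seeded generator (`sim_spec`,
  `simulate_genome`, `simulate_expression`, `simulate_homology`) that
  plants all of the above with a truth table, so the entire pipeline is
  testable without downloads.

## Worked example

```r
library(bicistroscan)

spec <- sim_spec(seed = 1, n_mono = 120, n_bicistron = 40)
sim  <- simulate_genome(spec)          # FASTA/GFF3-equivalent in memory
cls  <- classify_loci(sim$models)
table(cls$class)
#> bicistronic_exclusive         monocistronic
#>                    40                   120

mono_ids <- sim$truth$transcript_id[sim$truth$class == "monocistronic"]
halves   <- split_train_eval(mono_ids, seed = 1)     # train PWM on half
mods     <- setNames(sim$models, vapply(sim$models, `[[`, "", "transcript_id"))
site_of  <- function(tid) {
  rs <- extract_regions(mods[[tid]], sim$genome)
  cut_site_window(rs$mrna, rs$regions$orf1$start)
}
pwm <- build_kozak_pwm(unname(vapply(halves$train, site_of, character(1))))
pwm
#> kozak_pwm trained on 60 site(s); consensus: GCACCATGGGCGC
#> information content (bits): 0.18 0.35 0.27 0.33 0.78 1.8 1.8 1.8 0.64 0.12 0.1 0.14 0.02

bic_ids <- sim$truth$transcript_id[sim$truth$class == "bicistronic_exclusive"]
ratios  <- vapply(bic_ids, function(tid)
  locus_kozak_profile(extract_regions(mods[[tid]], sim$genome), pwm)$ratio,
  numeric(1))
median(ratios)
#> 0.53      # planted weak-ORF1 / strong-ORF2 contexts: ratio well below 1

bias <- region_bias_table(lapply(mods[bic_ids], extract_regions,
                                 genome = sim$genome))
round(bias$class_medians, 2)
#>    before_orf2 five_prime_utr      inter_orf           orf1           orf2
#>           0.76           0.00           0.37           1.01           1.10

tab   <- simulate_expression(spec, sim$truth)
bic   <- sim$truth[sim$truth$class == "bicistronic_exclusive", ]
pairs <- data.frame(id1 = bic$gene1, id2 = bic$gene2)
pair_correlation(tab, pairs, "rna")$r
#> 0.95      # the two ORFs share one transcript
occupancy_comparison(tab, pairs)
#> $greater 29; $n 40; $fraction 0.725   # ORF1 usually out-occupies ORF2
```

Reading the numbers: the median ORF1:ORF2 bit-score ratio of **0.53**
(vs ≈1 for monocistronic controls; Wilcoxon p ≈ 8e-14 on this seed) is
the leaky-scanning signature — ORF1 sits in a weak initiation context
relative to ORF2. The o/e medians show AUG depletion upstream of ORF2
(5' UTR 0.00, inter-ORF 0.37, cumulative "before ORF2" 0.76) but none
inside ORF2 itself (1.10). RNA abundances of the two ORFs are almost
perfectly correlated (r = 0.95) because they ride the same transcript,
while ribosome occupancy is usually higher on ORF1 (29/40 loci): only
the ribosomes that leak past ORF1 reach ORF2.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "bicistroscan.R", package = "bicistroscan"))')
Rscript $CLI simulate --seed 4 --outdir sim/ --n-mono 8 --n-bicistron 4
Rscript $CLI regions  --genome sim/genome.fa --gff sim/annotation.gff3 --out regions.tsv
Rscript $CLI detect   --genome sim/genome.fa --gff sim/annotation.gff3 --out loci.tsv --stats stats.tsv
Rscript $CLI kozak train --genome sim/genome.fa --gff sim/annotation.gff3 --seed 1 --out pwm.json
Rscript $CLI kozak score --genome sim/genome.fa --gff sim/annotation.gff3 --pwm pwm.json --out profiles.tsv
```

`augbias`, `conserve`, `express` and `audit` subcommands cover the
remaining modules (see the header of `inst/cli/bicistroscan.R`).

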