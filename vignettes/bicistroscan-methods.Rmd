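---
title: "Methods: detecting and characterising bicistronic loci under the leaky-scanning model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bicistronic locus analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Nuclear genes in eukaryotes are canonically monocistronic, yet green algae
carry dozens of loci whose mature mRNAs encode two independently translated
ORFs — each with its own start and stop codon, separated by a short
"inter-ORF" spacer — and whose transcripts are *exclusively* bicistronic
(no monocistronic isoform exists for either ORF). The working model for how
the downstream ORF gets translated is **leaky ribosomal scanning**: the
43S preinitiation complex scans from the 5' cap, and a suboptimal sequence
context around the ORF1 start codon lets a fraction of scanning complexes
pass it and initiate at ORF2 instead. Under this model one expects, and
this package tests for:

* a weak Kozak-like context at ORF1 relative to ORF2 and to monocistronic
  genes (ORF1:ORF2 bit-score ratio below 1);
* depletion of AUG 3-mers in everything upstream of the ORF2 start
  (5' UTR, ORF1, inter-ORF), because any AUG there competes for scanning
  ribosomes;
* short 5' UTRs;
* near-identical RNA abundance of the two ORFs (they share one transcript)
  but lower ribosome occupancy on ORF2 than ORF1;
* conservation of the two-ORF arrangement as colinear gene pairs in other
  genomes.

`bicistroscan` implements each of these analyses as a reusable,
synthetically testable pipeline, plus an auditor that applies the same
rules generatively to synthetic construct design.

## The scoring model

The initiation-context model is a position weight matrix over a 13-nt
window: five nucleotides upstream of the start codon, the invariant `AUG`,
and five nucleotides downstream (offsets −5..−1, +1..+3, +4..+8 with the
`A` at +1). For position $i$ with base probabilities $p_i(b)$, the
information content is the standard sequence-logo column height
$$R_i = 2 + \sum_b p_i(b)\,\log_2 p_i(b) \in [0, 2]\ \text{bits},$$
with $0 \log 0 = 0$. A candidate site $x$ scores the **mean letter
height** over the ten flanking positions:
$$\mathrm{score}(x) = \tfrac{1}{10}\sum_{i \in \mathrm{flanks}} p_i(x_i)\, R_i,$$
again on a 0–2 bit scale. Two modelling choices here were genuinely open:

* **AUG positions are excluded from scoring.** Including them would add a
  constant ≈2-bit term to every site and compress all ORF1:ORF2 ratios
  toward 1; the invariant codon carries no discriminative information.
* **Mean, not sum.** The mean keeps the score on the interpretable
  per-column [0, 2] scale, consistent with quoting a single weak site as
  "bit score 0.34".

Positions holding `N` (or falling off a transcript end — windows are
N-padded) are skipped and the mean renormalised; a site with more than 3
unscorable flanks returns `NA`. Training uses a pseudocount (default 0.5)
per base per position; no small-sample logo correction is applied because
intended training sets are in the thousands of sites.

Training follows a half-split protocol: half of the monocistronic genes
(`split_train_eval`, seeded) build the consensus PWM, the other half
provide the background score distribution, so evaluation scores are never
computed against a PWM that saw the same sites.

## AUG depletion statistics

For each region class (5' UTR, ORF1, inter-ORF, their concatenation
"before ORF2", ORF2; and UTR/ORF/sum for monocistronic genes) the
observed count of possibly-overlapping `ATG` 3-mers is compared to the
expectation under an i.i.d. base model,
$$E = (L - 2)\, p_A\, p_T\, p_G,$$
with the composition estimated either from the pooled sequence of the
region class (default — this is what "adjusted for the GC bias of the
sequence elements" means operationally) or per sequence (flag). The o/e
ratio is undefined for regions shorter than 3 nt. Both observed and
expected counts use the same window count $L-2$, which keeps o/e
internally consistent and makes it invariant to concatenation order
within "before ORF2". A length-validation statistic (Pearson r between
UTR+ORF length and observed count across monocistronic genes) is
reported alongside, mirroring the published sanity check that length is
the dominant predictor of AUG counts.

## Detection and structure

A locus is the connected component of transcripts sharing ORF (gene) ids.
It is *exclusively bicistronic* only if every isoform carries the same
two ORFs; any isoform carrying one alone, or more than two, demotes the
locus to `polycistronic_mixed` (tricistrons are reported but excluded).
uORFs are scanned in 5' UTRs as ATG..first-in-frame-stop intervals lying
entirely within the UTR (default minimum 9 nt: start + one codon + stop,
the smallest non-degenerate ORF; the choice is exposed). Colinear
monocistronic gene pairs — the control population throughout — are
same-strand neighbours within 20,000 nt (stop-to-start), with the
tighter ≤5,000/≤3,000-nt variants available as parameters.

## Conservation calls

Orthology is inferred by reciprocal best hit over tabular
(BLAST outfmt-6) protein hits, with bitscore ties broken
lexicographically so calls are deterministic and row-order invariant
(e-value ceiling 1e-5 by default). A bicistron is *colinear* in a target
genome when both ORFs' orthologs lie on the same strand of the same
chromosome, within 20,000 nt, with no same-strand gene between them;
opposite-strand interveners do not break adjacency (an open question in
the source material; chosen because scanning-based readthrough of the
arrangement is strand-local). Iso-Seq or EST support upgrades the call
tier but never creates a call.

## Expression correlations

RNA-Seq and Ribo-Seq per-ORF abundances are correlated on the log10
scale with pairwise exclusion of zero/missing values (a +1 pseudocount
mode exists behind a flag; exclusion is the default because no
pseudocount convention is given for the source data). The occupancy
comparison counts strict ORF1 > ORF2 inequalities (ties are
not-greater). The Kozak-vs-footprint relation summarises upstream
initiation strength as the *maximum* bit score over the ORF1 start and
all internal AUGs — the strongest competing site is what captures
scanning ribosomes — and correlates it against log(ORF2/ORF1 ribosome
occupancy); under leaky scanning this correlation is negative.

## Nonparametric statistics

`wilcoxon_rank_sum` enumerates the exact rank-sum distribution when
$n_x + n_y \le 12$ and no ties are present (two-sided
$p = 2\min(P(W \le w), P(W \ge w))$, capped at 1, which for the
symmetric tie-free null equals the symmetric-tail permutation
probability); otherwise it uses the normal approximation with tie and
continuity corrections. `kruskal_wallis` applies the standard tie
correction with a $\chi^2_{k-1}$ reference. No multiple-testing
correction is applied by default (none is stated for the pairwise tests
being mirrored); Benjamini–Hochberg is available via `adjust_bh`.

## The synthetic world

`sim_spec()` fixes a stated world whose defaults are the published
medians of the curated algal sets: 5' UTR 83 nt, ORF1 357 nt, ORF2
1,113 nt, inter-ORF 183 nt, monocistronic ORF 1,509 nt / UTR 214 nt
(log-normal, sdlog 0.5 — a spread chosen once as realistic for length
distributions spanning an order of magnitude); GC ≈ 0.64 composition;
AUG o/e targets of ~0.5 for UTRs and inter-ORFs and ~0.7 for ORF1
(thinning each AUG occurrence to the target in expectation); ORF1 sites
drawn from the weak tail (≤30th percentile) and ORF2 from the strong
tail (>70th) of the generator PWM's score distribution, monocistronic
sites from the middle band; planted RNA log-scale correlation r = 0.92;
and ribosome attenuation $\mathrm{ribo}_2 = \mathrm{ribo}_1
e^{-k\cdot\mathrm{strength}}\cdot\varepsilon$. The generator PWM is a
GC-biased consensus (purine at −3, C at −1, G at +4) whose sampled-site
scores span ≈0.05–0.17 bits; $k = 10$ and noise sd 0.8 were calibrated
*at design time* to that scale so the default world reproduces the
observed ≈0.9 fraction of loci with ORF1 > ORF2 occupancy. One
pseudo-chromosome carries all loci with log-normal intergenic spacers;
transcripts optionally carry 1–2 `GT..AG` introns so spliced-coordinate
code paths are exercised.

One subtlety worth knowing: the AUG-thinning targets are expressed
relative to the *generating* composition, but `region_bias_table`
re-estimates its expectation from the emitted (already thinned,
stop-codon-free) sequences. As with any GC-adjusted expectation, the
depletion partially hides itself, so realised class medians sit above
the thinning targets — UTRs and inter-ORFs still show clear depletion
(medians near 0 and ~0.4), while ORF-class medians drift toward 1.

What the generator does *not* emulate: transcription start heterogeneity,
overlapping genes, alternative splicing of the same locus, biased codon
usage, secondary structure around initiation sites, and read-level noise
(abundances are drawn at the ORF level). A green test therefore
establishes correctness of the *computations* on data with the assumed
statistical structure, not robustness to real annotation error.

## Numerical and representational choices

* Coordinates are 1-based inclusive throughout, matching GFF3 and the
  R/Bioconductor container conventions the package is built on; empty
  regions (e.g. a zero-length inter-ORF) are represented with
  `end = start - 1` and length 0.
* The GFF3 dialect encodes one ORF per distinct CDS `ID` under an mRNA;
  this is the loader's and writer's shared contract because GFF3 has no
  canonical encoding for two CDS groups on one mRNA. Stop codons are
  inside the CDS group, so the inter-ORF is exactly the gap between
  ORF1's stop and ORF2's start.
* Colinear spacing is reported as downstream ORF start minus upstream
  ORF end in genomic coordinates (the worked-example convention; it
  differs by 1 nt from the transcript-level inter-ORF gap and is
  immaterial to the medians it feeds).
* Reciprocal-best-hit ties and train/eval splits are the only stochastic
  or order-sensitive points outside the generators; both are pinned
  (lexicographic tie-break; seeded split).
* Rejection sampling of banded initiation sites aborts with an error
  naming the band after 10,000 failures rather than silently widening
  the band.

## Construct auditing

The auditor applies the leaky-scanning design rules as checks:
(i) 5' UTR length at or below the 50th percentile of the reference
length distribution, (ii) ORF1 context at or below the 40th percentile
of the monocistronic score distribution ("suboptimal"), (iii) no AUG
upstream of ORF2 besides the ORF1 start, (iv) ORF2 context at or above
the 60th percentile ("strong"). The percentile bands are configuration:
the underlying rules are qualitative and no quantitative bands are
published, so the defaults are deliberate, documented artifact choices.
`tune_kozak` searches substitutions exhaustively within an edit budget,
by default only upstream of the start codon so the encoded protein is
untouched; `suggest_aug_removal` proposes Met→Leu replacements for
in-frame internal AUGs (protein-changing, as in published reporter
designs) and synonymous substitutions for out-of-frame AUGs, marking a
3-mer unresolvable when no synonymous edit removes it.

## Known limitations

* The bit-score formula (mean letter height, AUG excluded) is one of
  several defensible readings of "WebLogo density bit scores"; ratios
  and rank-based comparisons are insensitive to the mean-vs-sum choice,
  but absolute scores are not comparable across conventions.
* Pooled-composition o/e expectation treats a region class as one bag of
  bases; strongly heterogeneous GC across loci would argue for the
  per-sequence flag.
* Colinearity uses gene-level adjacency only; it does not verify that
  the target orthologs are themselves co-transcribed.
* The exact Wilcoxon path enumerates only tie-free pooled samples up to
  size 12; tied small samples fall back to the corrected normal
  approximation.
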