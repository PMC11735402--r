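---
title: "Saturation genome editing screens: library design, scoring and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Saturation genome editing screens: library design, scoring and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgescreen)
```

## The experiment this package models

Saturation genome editing (SGE) introduces every possible variant of a target
region — for example the exons encoding the p53 DNA-binding domain — at the
endogenous locus of a pooled cell population via CRISPR-mediated homologous
recombination. After a selective treatment (such as a p53-activating MDM2
inhibitor), variants that inactivate the protein expand relative to
functionally neutral ones. Targeted amplicon sequencing of the edited region
before and after selection turns the phenotype of thousands of variants into
count data in one experiment.

`sgescreen` implements the complete dry-lab side of such a screen:

1. **Library design** — exhaustive enumeration of variants for each exon with
   its intronic flanks, including restriction-site silencing for Golden-Gate
   cloning.
2. **Counting** — exact matching of merged amplicon reads against the
   designed sequences.
3. **Scoring** — enrichment scores, control-anchored relative fitness scores
   (RFS), replicate aggregation and a one-sided test against the synonymous
   null.
4. **NMD detection** — mRNA/DNA abundance ratios identifying
   nonsense-mediated decay.
5. **Clinical calibration** — truth-set confusion metrics, PR/ROC curves,
   OddsPath evidence strength, Z′ factors, cross-screen rescaling, and
   mutational-signature probabilities.
6. **Structural features** — residue distances to defined reference surfaces
   of a protein–DNA complex.
7. **Simulation** — a seeded generator producing mini-genes, ground-truth
   fitness and replicate count tables with the statistical structure the
   analysis assumes, so every stage is testable without sequencing data.

## Transcript model and variant taxonomy

A `transcript_model()` holds a genomic stretch in transcript-strand
orientation, its exon intervals (0-based, half-open), the spliced CDS offset
and the protein position of the first codon. Each exon defines one *variable
region* — the exon plus `flank_len` intronic nucleotides (default 12) — framed
by `constant_len` (default 13) invariant nucleotides used for read trimming.
Internal introns are checked for canonical GT..AG dinucleotides.

`annotate_edit()` classifies any substitution, single-base insertion or 1–3 bp
deletion by re-splicing and re-translating the edited sequence:
`synonymous`, `missense`, `nonsense`, `frameshift`, `inframe_indel`,
`intronic` and `splice_dinucleotide` coding classes, plus a nucleotide-level
taxonomy (transition/transversion SNVs, 2- and 3-nt substitutions,
insertions, in-frame/frameshift deletions, intronic). Conventions worth
stating explicitly:

* **Splice dinucleotides take precedence**: any edit disrupting the first or
  last two bases of an intron is classified `splice_dinucleotide`,
  reflecting that GT/AG disruption abolishes splicing regardless of coding
  effect.
* **Boundary edits** touching both exonic and intronic bases are classified
  by their exonic effect and flagged (`boundary = TRUE`); how such variants
  behave in a real screen is ambiguous, and the flag preserves that
  ambiguity.
* **`introduces_ptc`** is computed by brute-force translation of the edited
  spliced sequence: `TRUE` when a stop appears strictly before the wild-type
  stop. Splice-site variants get `FALSE` because their true transcript is
  not predictable from sequence alone.
* **Indels are left-aligned** (VCF-style) so that homopolymer-ambiguous
  edits have one canonical representation; this makes deduplication and
  exact-match counting well defined.
* Standard nuclear genetic code throughout; no selenocysteine handling.

## Library enumeration

For each variable region `build_library()` applies four enumerations:

* all single-nucleotide substitutions (3 per position, `3L` total),
* multi-nucleotide codon exchanges completing every fully-internal codon to
  all 19 missense targets plus stop (and a synonymous exchange where no
  synonymous SNV exists), each chosen by `min_hamming_codon()` — the codon
  encoding the target at minimal Hamming distance from the reference,
  lexicographically smallest on ties (the tie rule is a package convention;
  only the minimal-distance priority is inherent to the design),
* every single-base insertion before each position (`4L` raw), and
* every 1–3 nt deletion (`3L − 3` raw).

Records are deduplicated by resulting sequence with precedence substitution
> deletion > insertion, then 5′-most, then alphabetical alternate allele —
a deterministic rule favouring the simplest mutational explanation of a
sequence. The wild-type sequence is excluded. Because two substitutions at
one position differ at exactly that position, the minimum pairwise Hamming
distance among equal-length library members is 1 — which is why downstream
counting must be exact-match: a 1-mismatch rescue would misassign reads
between adjacent variants.

Insertions are anchored *before* positions `0 … L−1`. An insertion after the
terminal variable-region base is representable as an insertion before the
first constant-frame base, i.e. it lies outside the variable region; this
convention keeps the `4L` closed form and all edits inside the region.
Codons for methionine and tryptophan have no synonymous partner and
therefore contribute no synonymous entries, and codons spanning exon
boundaries are excluded from the amino-acid enumeration, since such variants
cannot be built within a single exon's oligonucleotide.

`silence_motif()` (default BbsI, `GAAGAC`) runs before enumeration, removing
every occurrence of the recognition site on either strand by a synonymous
codon exchange (coding) or a single intronic base change, scanning 5′→3′
with alphabetical tie-breaks, never touching splice dinucleotides, and
verifying that no new occurrence is created and the protein is unchanged.

Note that the total library size for a real target depends on the actual
nucleotide sequence twice over: the set of SNV-reachable amino-acid changes
varies by codon, and homopolymer runs determine how many raw indels collapse
in deduplication. Reproducing a reference library count therefore requires
the exact target sequence, not just its geometry.

## Counting

`trim_to_variable_region()` matches both constant frames by anchored Hamming
comparison (tolerance configurable, default 0) and extracts the interior;
`count_reads()` assigns each interior to at most one variant by exact match.
Reads equal to the wild-type variable region are tallied and discarded —
wild-type alleles are not part of the measured library — and everything else
counts as unmatched. Per-sample accounting satisfies
`matched + wt_discarded + unmatched + flank_fail = reads_in`. FASTQ input
goes through `Biostrings`; base qualities are ignored because overlap-merged
reads are assumed error-corrected upstream.

## Scoring model

With relative abundances `f = matched count / total matched`, the enrichment
score of variant *v* is `ES_v = log2 f_treated(v) − log2 f_control(v)`;
in count mode frequencies are pseudocounted as `(c + 0.5)/(N + 0.5)`. The ES
scale depends on the library's composition of impaired and neutral variants,
so scores are normalized per exon to the **relative fitness score**

$$\mathrm{RFS}(ES) = \frac{ES - \tilde{x}_{non}}{\tilde{x}_{non} -
\tilde{x}_{syn}} \times 2 + 1,$$

an affine map taking the exon's nonsense-control median exactly to +1 and its
synonymous-control median exactly to −1 in every replicate. The per-exon
anchoring matters because each exon is a separate sub-library with its own
composition. Replicates are aggregated by the elementwise median
(`rfs_median`), with the raw median absolute deviation as dispersion.

For significance, `count_score_with_se()` provides a log-ratio score with a
Poisson-derived standard error,
`SE = (1/ln 2)·sqrt(1/(c₁+0.5) + 1/(c₀+0.5))`. `score_screen()` pools
per-replicate scores by fixed-effect inverse-variance weighting, transforms
the pooled score to the RFS scale (scaling its SE by the same affine slope),
and runs `syn_null_ztest()`: the null is that a variant's score is equal to
or lower than the *weighted mean* of the synonymous variants. The weights
are inverse-variance — the natural choice when scores carry per-variant
standard errors, though other weightings would be defensible; the resulting
upper-tail normal p values are Benjamini–Hochberg adjusted. Variants with
sparse control counts are flagged (`low_input`), not dropped, since no
principled universal cutoff exists.

## NMD detection

`nmd_log2fc()` compares a variant's median mRNA abundance with its median
genomic-DNA abundance (medians over replicates, pseudocounted frequencies as
in scoring) and classifies `NMD⁺` when the log2 ratio is strictly below −2
(boundary equality is negative). Variants with a mean raw cDNA count below 5
are marked not evaluable. The median-of-abundances-then-ratio order is a
deliberate choice: it matches how per-variant abundances are summarized
across biological replicates elsewhere in the pipeline.

One algebraic subtlety: abundances are relative, so depleting a fraction
*F* of variants *k*-fold inflates everyone else by
`1/(1 − F + F/k)`. The measured PTC log2 ratio is
`−log2 k − log2(1 − F + F/k)`; for a substitution-only library (*F* ≈ 0.06
nonsense variants) the shift is under 0.1 log2 units, while an indel-heavy
library (*F* ≈ 0.45 frameshifts) shifts both populations by ≈ +1. The
simulation-based recovery checks therefore use substitution-only libraries,
and real-data interpretation of absolute fold changes should keep the
renormalization term in mind — the −2 classification threshold, being far
from both populations, is robust to it.

## Clinical calibration

`classify_function()` calls a variant functionally abnormal when
`rfs_median > 0` — strictly positive scores lie closer to the nonsense
anchor. Zero was chosen as the natural midpoint of the anchor scale; it is
configurable, and an alternative of fitting the cutoff on controls is easy
to build but not the default since it changes the meaning of downstream
calibration. Against a pathogenic/benign truth set, `confusion_metrics()`,
`pr_roc()` (tie-grouped threshold sweep, trapezoidal AUC) and `oddspath()`
quantify classifier quality. OddsPath converts the confusion proportions to
the odds of pathogenicity:

$$P_1 = \frac{TP+FN}{N},\quad P_2 = \frac{TP}{TP+FP},\quad
\mathrm{OddsPath} = \frac{P_2(1-P_1)}{(1-P_2)P_1},$$

with `P2′ = FN/(FN+TN)` for the benign side. Strength labels use the
standard functional-evidence thresholds (supporting 2.08, moderate 4.33,
strong 18.7, very strong 350, reciprocals on the benign side), editable via
the `thresholds` argument. A zero misclassification cell yields infinite
odds; an optional 0.5 continuity correction gives finite values.

`z_prime()` summarizes control separation
(`Z′ = 1 − 3(σ₊+σ₋)/|μ₊−μ₋|`), `rescale_external_screen()` puts external
datasets on the same RFS scale (same affine construction) and labels
variants by quadrant in the two-screen plane (strictly positive = LOF side,
so the lower-right quadrant holds variants called LOF here but WT-like
externally), and `sbs_mean_probability()` averages COSMIC-style 96-channel
substitution signatures, weighted by prevalence, to estimate how likely each
SNV is to arise mutationally (channels on the pyrimidine strand via
`sbs_channel()`).

## Structural features

`load_structure()` wraps `bio3d`'s PDB parser (first model only, HETATM
flagged). `residue_distance_matrix()` offers minimum-heavy-atom distances
(contact-map semantics, the default) and a faster Cα mode — reference
contact-map tools do not always document their metric, so both are provided.
`mean_distance_to_set()` profiles residues against reference sets such as a
DNA-binding surface (for the p53 DBD: residues 248/273/277/280 on top,
153/225/260 at the bottom, 195/236/253 in the core, the defaults of
`structure_features()`); a residue belonging to its own reference set
contributes its zero self-distance, deterministically, with a flag.
`interface_residues()` returns residues with any heavy atom within a cutoff
(default 10 Å, inclusive) of a partner chain.

## The simulator: what it does and does not emulate

`sim_config()` fixes the study conditions: sequencing depth 500× per
variant, three biological replicates, selection strength `g = 2` (a variant
at the LOF anchor enriches 16-fold over one at the WT anchor — typical for a
strong selective treatment over ~8 days), fitness anchors at ±1 with
SD 0.15 for controls, a bimodal missense mixture (55% LOF component,
SD 0.3), in-frame indels near the LOF anchor (mean 0.8), 30-fold mRNA
depletion of PTC variants, and mild clone-size overdispersion (Dirichlet
concentration 50 per variant). Treated abundances are proportional to
`f₀ · 2^(g·fitness)`, making the expected ES linear in true fitness; reads
are multinomial draws at `depth × n_variants` per sample. All randomness
flows from the single config seed, so equal configs give bit-identical
output; optional FASTQ emission (`simulate_reads()`, error rate 0 by
default) exercises the counting path end-to-end.

The simulator reproduces the statistical structure the analysis assumes —
multinomial sequencing noise, clone-size variation, class-anchored fitness,
NMD depletion — but deliberately omits PCR jackpots, position-dependent
editing efficiency, sequencing-error structure beyond uniform substitution,
splice-isoform changes and selection kinetics. Passing recovery tests on
simulated screens therefore validates the *computational* pipeline, not the
robustness of any particular wet-lab protocol.

Default problem sizes in the test-suite simulations (two exons of 45–342 nt,
depths 200–500×) were chosen as the smallest instances at which the
asymptotic properties under test (type-I error calibration with ≥2,000
variants, rank-recovery ≥0.9, NMD recall ≥95%) are comfortably expressed.

## Numerical choices and limitations

* Pseudocount 0.5 on raw counts throughout (a standard log-ratio
  convention); pure-frequency mode requires nonzero control frequencies.
* Median-based anchors are exact by construction, not approximately: tests
  assert the ±1 anchors to machine precision (for even-sized control sets
  the median averages two transformed values, so equality holds to floating
  point, not bitwise).
* Degenerate inputs fail loudly: equal control medians, empty control sets,
  all-zero samples, zero SEs and single-class truth sets raise errors rather
  than returning silent NAs.
* The z-test assumes approximately normal log-ratio scores with known SEs;
  at very low counts the Poisson-derived SE is conservative.
* No multi-transcript support, no genome-wide annotation, no alignment, no
  UMI handling, no splice-isoform reconstruction; cross-cell-line
  meta-analysis and time-course scoring are out of scope.
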