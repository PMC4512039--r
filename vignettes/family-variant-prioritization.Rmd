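---
title: "Recessive-model variant prioritization in affected sibships: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recessive-model variant prioritization in affected sibships: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadscreen)
```

## The problem and the model

Two siblings concordant for a rare disease, sequenced together with their
healthy parents, support a recessive working model: each affected child
carries two disadvantaging alleles at some locus — either the same allele
twice (homozygous, one copy from each carrier parent) or two different
alleles in the same gene, one from each parent (compound heterozygous, in
trans). `quadscreen` operationalizes this as a cascade of set filters over
biallelic sites followed by gene-level classification.

The cascade assumes unphased genotypes. Phase is *inferred* where the
pedigree determines it: for a shared heterozygous site we enumerate which
parent(s) could have transmitted the alternate allele given both parental
genotypes. A homozygous-alternate mother, for example, necessarily
transmitted the alternate, whatever the father carries. This is stronger
than the naive "which parent carries the allele" heuristic and it changes
conclusions: a gene with two shared heterozygous variants can have both
resolve to the *same* parent, in which case both alleles arrived on a single
transmitted haplotype and a trans configuration cannot be claimed. We class
such genes — together with genes where both parents are heterozygous at both
sites and phase is genuinely unknowable from the trio — as
`compound_het_ambiguous`, distinct from `compound_het`, which is only
assigned when at least one site is definitively paternal and another
definitively maternal. Published candidate tables typically do not make this
distinction; report sections therefore group both classes under the
compound-heterozygous heading while the class column preserves it. The
shipped case study contains exactly one such gene (*PDE4DIP*: one site with
a heterozygous father and homozygous-alternate mother, one with a carrier
mother only — both alleles maternal).

Sibling sharing defaults to the *identity* rule (same unordered allele pair
in every affected sib), because a shared causal genotype is what the
recessive model predicts and because the case-study source table prints a
single genotype column for the sibship. An any-carrier rule is available
(`shared_rule = "carrier"`) for designs where sibs may differ in zygosity.

Missing genotypes are removed rather than imputed (`missing_policy =
"strict"`): a site with any missing call in the sibs or parents leaves the
cascade at QC. The lenient mode keeps such sites and lets missing calls pass
the Mendelian stage as unknowns; they still cannot be classified, since
classification requires concrete genotypes. Strict is the default because
the cascade's purpose is noise *reduction*, and a trio with a missing member
cannot certify consistency.

## Thresholds

All tunable thresholds live in `default_thresholds()` and surface through
`reduction_config()` and the pipeline config file:

| parameter | default | units | role |
|---|---|---|---|
| `sift_max` | 0.05 | SIFT score | damaging iff score ≤ cutoff (inclusive) |
| `polyphen2_min` | 0.957 | PolyPhen-2 score | damaging iff score ≥ cutoff (inclusive) |
| `fathmm_max` | −1.5 | FATHMM score | damaging iff score < cutoff (strict) |
| `rare_maf` | 0.001 | allele frequency | "extremely rare" cap on max available MAF |
| `common_cap` | 0.10 | allele frequency | cap on the frequent member of a compound-het pair |
| `q2_cap` | 0.05 | genotype frequency | cap on population homozygote frequency q² |
| `siphy_min` | 10 | SiPhy score | conservation flag (report-only) |

The three tool boundaries are applied exactly as published for these tools —
note the deliberate asymmetry, FATHMM strict, the other two inclusive — and
the boundary behaviour is pinned by tests. Rarity is judged on the
*maximum* across the available population frequencies (rare everywhere, the
conservative reading when multiple databases are cited). Missing frequencies
count as rare with the basis recorded as `missing_treated_rare`: in this
workflow absence from the databases is evidence of rarity, the same logic
the de novo screen uses for privateness.

Two rarity choices deserve justification:

* **Homozygous candidates are judged on q², not MAF.** A recessive genotype
  can be population-relevant even when the allele itself is not rare; what
  must be rare is the homozygote. The 0.05 default keeps a homozygote seen
  in 2.5 % of a reference population while excluding one seen in 44 %.
* **Compound-het pairs need one extremely rare member, with every member
  below `common_cap`.** Requiring both members rare would discard real
  pairs in which one allele is a low-frequency polymorphism; requiring
  none would flood the report. The pair semantics are configuration, not
  hard-coded, and are applied jointly to the pair rather than per variant.

The consensus stage requires each candidate variant to be called damaging by
at least `min_damaging = 1` of the three tools *among those with a score*;
variants with no scores at all pass unassessed rather than being silently
dropped. One-of-three is deliberately permissive: the tools disagree often,
and the precedent this pipeline follows treats a single confident tool as
sufficient to retain a rare variant for expert review.

## The de novo branch

Shared de novo candidates (germline mosaicism) are definitionally
Mendelian-inconsistent, so the screen runs as a parallel branch on the
unfiltered input. A site qualifies when (a) every affected sib carries the
alternate, (b) neither population database records a frequency for it — a
recorded frequency of zero still counts as a database entry — (c) neither
parent has a single alternate-supporting read, and (d) both parents are
covered at ≥ `min_parent_depth = 8` reads, so that the absence of evidence
is evidence. Sites failing each criterion are counted separately
(`attr(x, "counts")`), including sites unassessable for lack of parental
depth information.

## Karyotypes

`parse_iscn()` handles the numeric-prefix ISCN form used in clinical
reports, restricted to whole-chromosome gains and losses; structural
rearrangement tokens ride along verbatim as notes, uninterpreted. The modal
number recomputes as 46 + gains − losses and a disagreement with the
declared prefix is flagged, never corrected. The ploidy bands (high
hyperdiploidy 51–67) are the conventional cytogenetic bands, not derived
from any dataset, and are overridable.

## What the simulator emulates — and what it does not

`simulate_sites()` draws a site-frequency mixture (30 % rare with MAF
log-uniform on [1e−5, 1e−3], the rest uniform on [0.01, 0.5]),
chromosome-coherent gene assignment, consequence labels, and tool scores in
the benign range by default. `simulate_family()` draws parents from
Hardy-Weinberg, transmits fair gametes (male children receive only the
maternal X), applies a per-call flip error (with probability ε the observed
diploid genotype is replaced by one of the other two, uniformly; hemizygous
calls flip), and draws Poisson depths with binomial alternate-read counts.
The depth means (sibship 28.1×, parents 19.4×) mirror the sequencing-run
coverages of the motivating study.

Because sibling genotypes are independent given the parents and sites are
independent, sharing and inconsistency probabilities are *analytic*, and the
test suite exploits this: observed Mendelian-inconsistency counts are
compared against an exact enumeration of flip outcomes, and sib-sharing
fractions against the exact transmission probability, both within 3
Monte-Carlo standard errors.

Deliberately not emulated: linkage disequilibrium and within-gene haplotype
structure (sites are independent), population stratification, depth-dependent
genotype error, multiallelic sites, indel length distributions, and any
correlation between allele frequency and deleteriousness score. Passing the
recovery suite therefore demonstrates the *logic* of the cascade — spiked
configurations are recovered perfectly at ε = 0 and nothing else passes at
default thresholds when background scores are benign — not its behaviour on
the correlated noise of real exomes.

Validation problem sizes, chosen to make the statistical checks sharp while
keeping the default suite quick: 200 simulated quads of 1,000 sites each for
spike-in recovery (one scenario per quad, cycling through compound-het,
homozygous, de novo and X-linked); 8 × 2,000 site-trios per error rate for
the ε ∈ {0.001, 0.01} inconsistency calibration; 3,000 sites for the
sharing oracle.

## Numerical and degenerate-input choices

* Coordinates are 1-based VCF coordinates throughout; no half-open
  conversion anywhere.
* Multiallelic records split into one site per alternate allele; at the
  site for allele *j*, allele *j* maps to 1 and all others to 0, which
  conserves summed alternate dose — the invariant the round-trip tests pin.
* Male X genotypes are normalized to hemizygous even when diploid-encoded;
  a *heterozygous* male X call is biologically impossible and becomes a
  missing call with a warning, not an error.
* Y and mitochondrial sites are unsupported by the trio logic and are
  removed at QC; calling the Mendelian check on them directly is an error.
* Gene symbols come from the annotation table and are authoritative: one
  candidate per symbol, case-insensitive panel matching, composite symbols
  ("FANCP/SLX4") matching on either component via the alias table.
* The Mendelian and shared-by-affected stages are pure set filters, so
  their order only changes the trace counts; `stage_order` exposes the
  permutation and a test pins result-identity.
* An empty VCF flows through the whole pipeline to an empty report with an
  all-zero trace rather than erroring.

## Fixture provenance

The shipped case study is a *reconstruction* of a published family report:
genotypes re-encoded as VCF records, annotations transcribed into the TSV.
Where the source table's typography was ambiguous (a handful of cells carry
stray characters; one row's allele orientation conflicts with its printed
homozygote frequency), the fixture records the Mendelian-consistent reading
consistent with the row's section, and the susceptibility-locus genotypes
ship as an rsid-keyed table because the source prints no coordinates for
them. These choices affect display only, not any verdict the tests assert.

## Known limitations

* Compound-het phasing uses trio transmission only; unrelated-cohort or
  read-backed phasing is out of scope, so `compound_het_ambiguous` genes
  stay ambiguous even when long reads could resolve them.
* The cascade starts from called genotypes; no BAM/pileup handling, no
  caller-quality recalibration, no structural variants, and left-alignment
  is the only indel normalization.
* Carrier counting treats missing cohort genotypes as non-carriers, which
  matches how published denominators include incompletely covered samples
  but will undercount in low-coverage cohorts.
* The deleteriousness tools are ingested as annotations; nothing is
  recomputed from sequence, and score versions are the user's
  responsibility.
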