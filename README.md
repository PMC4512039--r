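# quadscreen

Family-based rare-variant prioritization for exome-sequenced nuclear families
with multiple affected siblings — the canonical design being a **quad**: two
affected sibs plus both parents.

Sibships concordant for a rare disease are a powerful setting for finding
inherited predisposing variants: parental genotypes let you (i) discard
Mendelian-inconsistent calls as sequencing artefacts, (ii) keep only variants
shared by every affected sib, and (iii) phase candidate genes by parental
transmission under a recessive disease model. `quadscreen` implements this
data-reduction cascade as a tested, reusable pipeline, together with the
satellite analyses such a study needs (gene-panel screening, cohort carrier
lookups, karyotype parsing) and a seeded synthetic quad generator so every
stage is testable with known truth and no external data.

## The model

Starting from called genotypes (multi-sample VCF + PED pedigree + per-variant
annotation table), sites are pushed through ordered set filters:

1. **QC** — supported chromosomes (autosomes + X), missing-genotype policy.
2. **Mendelian filter** — a child genotype must be producible by one gamete
   from each parent (autosomes), or by a single maternal gamete for a male
   child on the X. Verified against brute-force gamete enumeration on all 27
   autosomal and 18 male-X trio genotype combinations.
3. **Shared by affected** — identical non-reference genotype in every
   affected sib (a looser any-carrier rule is available).
4. **Consequence** — non-synonymous (missense, stop-gain) and frameshift only.
5. **Recessive classification** per gene:
   * `homozygous_recessive` — sibs homozygous-alternate, both parents carriers;
   * `compound_het` — ≥ 2 shared heterozygous sites whose alt alleles resolve
     to *opposite* parents (trans configuration), by enumerating the
     transmissions consistent with the parental genotypes;
   * `compound_het_ambiguous` — ≥ 2 shared het sites whose origins cannot be
     resolved to opposite parents;
   * `x_hemizygous` — male sibs alternate-hemizygous on X with a carrier mother.
6. **Rarity + deleteriousness consensus** — per-tool damaging calls at
   SIFT ≤ 0.05, PolyPhen-2 ≥ 0.957, FATHMM < −1.5; rarity on
   max(MAF₁₀₀₀G, MAF_ESP) ≤ 0.001 for heterozygous-type candidates, on the
   population homozygote frequency q² ≤ 0.05 for homozygous candidates, and a
   one-rare-member / all-members ≤ 0.10 rule for compound-het pairs. SiPhy
   conservation (≥ 10) is annotated but never filters.

A **de novo branch** runs on the unfiltered input: private variants (no
recorded population MAF) shared by the sibs, with zero alternate-supporting
reads in either parent at ≥ 8× parental coverage.

Every stage logs input/output counts in a filter **trace**, the audit
artifact of the run.

## Worked example

The package ships a reconstructed quad case study (two brothers with
concordant hyperdiploid pre-B acute lymphoblastic leukemia and their healthy
parents) under `inst/extdata`: 17 shared recessive candidate variants with
genotypes and annotations.

```r
library(quadscreen)
ex  <- load_quad_example()
red <- run_reduction(ex$fam, ex$ped, ex$ann)
red
#> Reduction cascade:
#>               stage n_in n_out
#>                  qc   17    17
#>           mendelian   17    17
#>  shared_by_affected   17    17
#>         consequence   17    17
#>      classification   17    17
#>    rarity_consensus   17     3
#> 11 candidate gene(s); 2 pass rarity + consensus; 0 de novo site(s)
```

Eleven genes classify — 4 in the compound-heterozygous section, 7 homozygous
— but only two survive the rarity + consensus stage: the Fanconi anemia gene
*FANCP/SLX4* (compound heterozygote, one allele from each parent, SIFT and
PolyPhen-2 damaging for both) and the Holliday-junction resolvase *GEN1*
(homozygous, q² = 0.025):

```r
subset(quadscreen:::flatten_candidates(red$candidates), passes,
       select = c(gene, klass, origins, rare, min_n_damaging))
#>          gene                klass           origins rare min_n_damaging
#>    FANCP/SLX4         compound_het paternal;maternal TRUE              2
#>          GEN1 homozygous_recessive                 . TRUE              1

restrict_to_panel(red$candidates, fa_panel())$gene
#> [1] "FANCP/SLX4"

karyotype_summary(c(sibA = "53,XY,+4,+6,+12,+15,+17,+18,+21",
                    sibB = "54,XY,+X,+5,+8,+10,+14,+17,+18,+21"))[, 1:5]
#>    id declared computed mismatch            ploidy
#>  sibA       53       53    FALSE high-hyperdiploid
#>  sibB       54       54    FALSE high-hyperdiploid
```

`run_pipeline()` drives the same cascade from a YAML/JSON config over files
and writes `report.tsv`, `report.json` (schema-validated) and `trace.tsv`;
`inst/scripts/quadscreen` wraps it for the shell (`run`, `simulate`,
`karyotype`, `carriers`).

## Synthetic quads

`sim_config()` / `simulate_sites()` / `simulate_family()` generate seeded
exome-like quads: a rare/common MAF mixture, Hardy-Weinberg parents, fair
Mendelian transmission, per-call genotype flip error, Poisson depths
(sibship 28.1×, parents 19.4×), and spike-ins for the four disease
scenarios (`compound_het`, `hom_recessive`, `de_novo`, `x_linked`) recorded
as ground truth. `write_fixture()` emits loader-ready VCF/PED/TSV/JSON.

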