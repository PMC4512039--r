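Package: quadscreen
Title: Family-Based Rare-Variant Prioritization for Quad Exome Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-reduction pipeline for prioritizing inherited rare variants in
    nuclear families with multiple affected siblings sequenced together with
    both parents (the canonical case being a quad: two affected sibs, father,
    mother). Implements Mendelian-inconsistency filtering, shared-by-affected
    reduction, recessive-model classification (homozygous and compound
    heterozygous with parental-origin phasing), X-linked and de novo screens,
    rarity and deleteriousness-consensus annotation (SIFT, PolyPhen-2, FATHMM,
    SiPhy), gene-panel screening (Fanconi anemia panel), cohort carrier
    counting, ISCN karyotype parsing, and a seeded synthetic quad-family
    generator with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
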