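Package: tadote
Title: Toxin-Antidote Gamete-Killer Genetics for Rice Hybrid Sterility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models tightly linked toxin-antidote (gamete-killer) loci of the
    kind that underlie hybrid male sterility between cultivated rice (Oryza
    sativa) and its wild relatives, such as qHMS1 and qHMS7. Provides exact
    computation of male gamete survival under a sporophytic toxin and a
    cis-acting gametophytic antidote with per-locus killing efficiency and
    stage-resolved pollen abortion; progeny genotype distributions for
    crosses, selfs and pedigrees; maximum-likelihood estimation of killing
    efficiency and female-transmission weights from genotype count tables
    with profile-likelihood and bootstrap intervals; deterministic and
    Wright-Fisher forward dynamics of toxin-antidote haplotypes; rule-based
    typing of toxin/antidote alleles from toy sequences with survey
    summaries and cross-compatibility prediction; and seeded generators for
    all synthetic inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
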