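Package: sonicload
Title: Genetic Load of Virtual Crosses and Its Sonification by Melody Detuning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes realised and masked genetic load of diploid individuals
    from deleterious-variant genotypes weighted by mutation-impact scores
    (CADD-like), aggregated per genome scaffold. Enumerates virtual Mendelian
    crosses between sequenced founders (including selfing), predicts the
    expected realised load of their offspring per scaffold, and quantifies the
    shared load between prospective parents. Each offspring's per-scaffold
    load profile can be sonified by detuning successive notes of a familiar
    monophonic melody via MIDI pitch-bend messages, written to a Standard MIDI
    File. A gamified evaluation layer ranks candidate offspring, scores survey
    responses against the truth and tests aggregate listener performance with
    an exact binomial test. A synthetic-data module generates founder
    populations, melodies and survey responses for end-to-end use without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    tibble,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
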