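Package: latemmr
Title: Late Mismatch-Response Endophenotype Extraction and Genetic Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the late component of the auditory mismatch
    response (MMR) as an endophenotype for dyslexia-related spelling deficits.
    Simulates passive oddball EEG experiments (stimulus sequences, continuous
    multichannel EEG with condition- and genotype-dependent event-related
    potentials, artifacts, genotypes in Hardy-Weinberg equilibrium, and
    spelling phenotypes), reduces continuous EEG to per-subject late-MMR
    amplitudes (re-referencing, zero-phase filtering, decimation, epoching,
    baseline correction, amplitude-based artifact rejection), performs
    genotype quality control and LD-based clumping, fits per-SNP additive
    linear models with Benjamini-Hochberg FDR control and QQ confidence
    envelopes, builds unweighted polygenic risk scores and evaluates
    classification improvement (ROC AUC with DeLong intervals, continuous net
    reclassification improvement, integrated discrimination improvement), and
    computes linear-model power. Includes EDF, VCF and TSV interchange and an
    end-to-end reproducible pipeline driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    jsonlite,
    pROC,
    signal,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
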