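Package: stresspatterns
Title: Template-Pattern Analysis of Hippocampal Transcriptional Adaptation to Chronic Stress
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for genotype-dependent adaptation to chronic
    mild stress in inbred mouse strains. Classifies hippocampal transcripts
    responding to a novel acute stressor after chronic mild stress using
    template response patterns (transient 0:1:0 and sustained 1:1:0 over
    CMS:CMS-R:NH-R groups), partitions stress-responsive calls across strains
    into Venn regions with direction-concordance scoring and hierarchical
    clustering, computes phenotype statistics (Type III two-way ANOVA with
    eta-squared, Welch contrasts, 2-SD outlier removal, fecal corticosterone
    time-course analysis), and performs hypergeometric over-representation
    analysis against gene-set collections. Includes seeded synthetic-data
    generators with planted ground truth for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    car,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
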