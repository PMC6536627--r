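#!/usr/bin/env Rscript
# Step 1: generate the synthetic study data.
#
# Emulates the design of the chronic-stress cross-sensitization study:
# 3 strains (B, N, D) x 4 treatment histories (NH, CMS, NH-R, CMS-R),
# 5 expression replicates per cell, 25,858 transcripts with planted
# transient/sustained stress templates, plus animal-level phenotype and
# weekly fecal-CORT tables. All outputs land under results/data/.

library(stresspatterns)

seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)  # full-scale defaults: 25,858 transcripts
sim <- simulate_expression(cfg)
cat(sprintf("expression: %d transcripts x %d samples, %d planted transcript-strain pairs\n",
            nrow(sim$matrix), ncol(sim$matrix), nrow(sim$truth)))

write_expression(sim$matrix, file.path(out, "expression.tsv"))
write_samples(sim$samples, file.path(out, "samples.csv"))
utils::write.table(sim$truth, file.path(out, "planted_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

pcfg <- pheno_config(seed = seed)
pheno <- simulate_phenotypes(pcfg)
fcort <- simulate_fcort_timecourse(pcfg)
cat(sprintf("phenotypes: %d animals; fCORT: %d weekly measurements\n",
            nrow(pheno), nrow(fcort)))
utils::write.csv(pheno, file.path(out, "phenotypes.csv"), row.names = FALSE)
utils::write.csv(fcort, file.path(out, "fcort.csv"), row.names = FALSE)

sets <- simulate_gene_sets(sim$truth, rownames(sim$matrix), seed = seed)
write_gmt(sets, file.path(out, "gene_sets.gmt"))
write_config(list(seed = seed, n_transcripts = cfg$n_transcripts),
             file.path(out, "run_config.yaml"))
cat("wrote", out, "\n")
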