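#!/usr/bin/env Rscript
# Step 4: phenotype statistics.
#
# Treatments are pooled into CMSgroup vs NHgroup (restraint does not
# affect biometrics); body-weight change and raw organ weights are
# analyzed by strain x treatment Type III ANOVA with eta-squared; plasma
# CORT is screened by the within-group 2-SD outlier rule first; Welch
# contrasts probe the cross-sensitization question; weekly fCORT is
# log-transformed and analyzed by strain x week ANOVA.

library(stresspatterns)

out <- "results"
pheno <- utils::read.csv(file.path(out, "data", "phenotypes.csv"))
fcort <- utils::read.csv(file.path(out, "data", "fcort.csv"))

pheno <- pool_groups(pheno)
pheno <- body_weight_change(pheno)

measures <- c("bw_change", "adrenal_mg", "thymus_mg", "heart_mg",
              "brain_g", "plasma_cort")
anova_tab <- do.call(rbind, lapply(measures, function(m) {
  vals <- pheno[[m]]
  keep <- rep(TRUE, length(vals))
  if (m == "plasma_cort") {
    scr <- remove_outliers(vals, paste(pheno$strain, pheno$treatment), k = 2)
    keep <- scr$kept
    cat(sprintf("plasma CORT: removed %d outlier(s) beyond 2 SD\n",
                nrow(scr$removed)))
  }
  res <- anova2_type3(vals[keep], pheno$strain[keep], pheno$pooled_group[keep],
                      names_ab = c("strain", "treatment"))
  cbind(measure = m, res)
}))
utils::write.table(anova_tab, file.path(out, "phenotype_anova.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nheart weight ANOVA (Type III):\n")
print(anova_tab[anova_tab$measure == "heart_mg", ], row.names = FALSE)

hw <- welch_t(pheno$heart_mg[pheno$pooled_group == "NHgroup"],
              pheno$heart_mg[pheno$pooled_group == "CMSgroup"])
cat(sprintf("\nheart CMS deficit: %.1f mg [Welch t(%.1f) = %.2f, p = %.2g]\n",
            hw$mean_a - hw$mean_b, hw$df, hw$t, hw$p))

# cross-sensitization: CMS-R vs NH-R plasma CORT within strain
for (s in unique(pheno$strain)) {
  w <- welch_t(pheno$plasma_cort[pheno$strain == s & pheno$treatment == "CMS-R"],
               pheno$plasma_cort[pheno$strain == s & pheno$treatment == "NH-R"])
  cat(sprintf("strain %s CMS-R vs NH-R CORT: diff %.0f ng/mL, t(%.1f) = %.2f, p = %.3f\n",
              s, w$mean_a - w$mean_b, w$df, w$t, w$p))
}

fc_res <- fcort_analysis(fcort)
utils::write.table(fc_res, file.path(out, "fcort_anova.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nfCORT strain x week ANOVA (log scale):\n")
print(fc_res, row.names = FALSE)
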