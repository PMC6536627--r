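#!/usr/bin/env Rscript
# Step 5: over-representation analysis of strain-specific call sets.
#
# Each strain's passing transcripts are tested against the gene-set
# collection with the full 25,858-transcript universe as background;
# categories need >= 5 in-background members, and significance is BH-
# adjusted p < 0.05.

library(stresspatterns)

out <- "results"
calls <- utils::read.delim(file.path(out, "calls.tsv"))
mat_ids <- utils::read.delim(file.path(out, "data", "expression.tsv"),
                             colClasses = "character")[[1]]
sets <- read_gmt(file.path(out, "data", "gene_sets.gmt"))

res <- do.call(rbind, lapply(unique(calls$strain), function(s) {
  target <- calls$transcript[calls$passes & calls$strain == s]
  if (length(target) == 0) return(NULL)
  r <- ora(target, mat_ids, sets, min_size = 5, alpha = 0.05)
  cbind(strain = s, r)
}))
utils::write.table(res, file.path(out, "enrichment.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

sig <- res[res$significant, ]
cat(sprintf("%d significant category hits across strains:\n", nrow(sig)))
print(sig[, c("strain", "category", "set_size", "overlap", "q")],
      row.names = FALSE)
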