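#!/usr/bin/env Rscript
# Step 3: cross-strain overlap, direction concordance, and clustering.
#
# Passing calls are partitioned into the 7 exclusive Venn regions of the
# three strains; shared transcripts are scored for direction concordance
# per strain pair and triple, and clustered on their per-strain CMS-R -
# NH-R contrasts (average linkage, Euclidean distance).

library(stresspatterns)

out <- "results"
calls <- utils::read.delim(file.path(out, "calls.tsv"))
mat <- read_expression(file.path(out, "data", "expression.tsv"))
samples <- read_samples(file.path(out, "data", "samples.csv"), mat)
strains <- unique(samples$strain)

part <- partition_calls(calls, strains)
print(part)
sizes <- region_sizes(part)
utils::write.table(
  data.frame(region = names(sizes), n = as.integer(sizes)),
  file.path(out, "overlap_regions.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE
)

combos <- c(utils::combn(strains, 2, simplify = FALSE), list(strains))
for (cc in combos) print(concordance(part, cc))
conc <- do.call(rbind, lapply(combos, function(cc) {
  s <- concordance(part, cc)
  data.frame(strains = paste(cc, collapse = ":"),
             n_overlapping = s$n_overlapping,
             n_same_direction = s$n_same_direction)
}))
utils::write.table(conc, file.path(out, "concordance.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cl <- cluster_overlap(mat, samples, part)
writeLines(cl$newick, file.path(out, "dendrogram.nwk"))
cat(sprintf("clustered %d shared transcripts; first leaves: %s ...\n",
            length(cl$leaf_order), paste(head(cl$leaf_order, 3), collapse = ", ")))
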