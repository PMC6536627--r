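# stresspatterns

Genotype shapes how animals adapt to chronic stress. In a design with
three inbred mouse strains — C57BL/6J (**B**), C57BL/6NJ (**N**) and
DBA/2J (**D**), spanning near-identical substrains (B vs N) and a highly
divergent pair (B vs D) — females experience either 7 weeks of chronic
mild stress (CMS) or normal housing (NH), optionally followed by a novel
15-min acute restraint (CMS-R, NH-R). The question is whether prior
chronic stress rewires the hippocampal transcriptional and
hypothalamic-pituitary-adrenal (HPA) response to a new stressor
(cross-sensitization), and how strongly that depends on strain.

`stresspatterns` implements the full analysis as a tested R package plus
a numbered analysis workflow:

- **Template-pattern classification** (`call_stress_transcripts`). For
  each transcript within each strain, log2 expression over the ordered
  groups (CMS, CMS-R, NH-R) is fit to two predicted templates — transient
  `0:1:0` and sustained `1:1:0` for up-regulation, with their inverses
  `1:0:1` / `0:0:1` encoding down-regulation. The fit regresses
  expression on the binary template indicator, so the slope t-test (df =
  n − 2) is exactly the pooled two-sample t-test and the inverse patterns
  are sign flips. Calls require nominal template p ≤ 0.05, a Welch NH-R
  vs CMS-R contrast p < 0.05, and a linear-scale change
  `2^(Δ mean log2) − 1` strictly above 10%. BH q-values are reported per
  strain but are descriptive, not gating. A 1-df chi-square
  `(n_up − n_down)² / (n_up + n_down)` tests direction bias per strain.
- **Cross-strain overlap and concordance** (`partition_calls`,
  `concordance`, `cluster_overlap`): the exclusive 7-region Venn
  partition of per-strain call sets, same-direction concordance for
  strain pairs and the triple, and average-linkage hierarchical
  clustering of shared transcripts on their per-strain CMS-R − NH-R
  contrasts (Newick export).
- **Phenotype statistics** (`pool_groups`, `anova2_type3`, `welch_t`,
  `remove_outliers`, `fcort_analysis`): CMSgroup/NHgroup pooling,
  body-weight change, Type III two-way ANOVA (sum-to-zero contrasts, via
  `car::Anova`) with η² = SS_term / SS_total, Welch contrasts, single-pass
  2-SD within-group outlier screening, and the log-transformed fecal-CORT
  strain × week ANOVA.
- **Enrichment** (`ora`): hypergeometric over-representation of a target
  list against the 25,858-transcript universe, categories ≥ 5 in-background
  members, BH-adjusted p < 0.05.
- **Synthetic data with planted truth** (`sim_config`,
  `simulate_expression`, `simulate_phenotypes`,
  `simulate_fcort_timecourse`): seeded generators that emulate the study
  design (3 × 4 cells, 5 replicates, planted templates with
  strain-specific membership, direction bias, overlap blocks and pairwise
  concordance; biometric orderings and fCORT habituation), returning the
  ground-truth labels used for calibration and recovery testing.

## Worked example

```r
library(stresspatterns)

cfg <- sim_config(n_transcripts = 2000, seed = 42)
sim <- simulate_expression(cfg)
calls <- call_stress_transcripts(sim$matrix, sim$samples,
                                 alpha = 0.05, fc_threshold = 0.10)
direction_bias_test(calls, "D")
#>   strain n_up n_down    chisq            p
#> 1      D  131    207 17.08876 3.567285e-05
part <- partition_calls(calls)
print(part)
#> Overlap partition over strains: B, N, D
#>     B     N     D   B:N   B:D   N:D B:N:D
#>   100    79   156    10    37   134    11
#> union: 527   multi-strain: 192
concordance(part, c("B", "N"))
#> B & N: 16 of 21 overlapping transcripts concordant (6 up, 10 down)
```

The D strain calls are down-biased (207 down vs 131 up, chi-square p ≈
4·10⁻⁵), the planted overlap blocks (9, 31, 130, 6 plus chance
co-calls) are recovered, and most shared B–N transcripts respond in the
same direction — the generator's planted structure, recovered end to end.

The numbered drivers run the whole study at full scale and narrate their
findings:

```sh
Rscript analysis/01_simulate.R    # expression + phenotypes + fCORT + gene sets
Rscript analysis/02_patterns.R    # template calls, direction bias, recovery
Rscript analysis/03_overlap.R     # Venn partition, concordance, dendrogram
Rscript analysis/04_phenotypes.R  # ANOVAs, Welch contrasts, fCORT time course
Rscript analysis/05_enrichment.R  # over-representation of strain-specific sets
```

All tables land under `results/`. `run_pipeline()` performs the same
end-to-end run programmatically and writes a manifest.

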