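# sdesr

Sex-dimorphic expression scoring and pathway enrichment for toxicogenomic
time courses.

## What problem this solves

In a toxicogenomic study — several chemicals applied to male and female
animals, replicated expression profiling at several exposure times, with a
matched untreated control group — some genes respond to *every* chemical in
*opposite* directions in the two sexes: up in males, down in females, or
vice versa. `sdesr` identifies those genes, quantifies how strongly a whole
time point's transcriptional response is organised by sex, tests which
metabolic pathways concentrate the dimorphic genes, and places those
pathways on a cross-talk network. It is written for analysts working with
two-colour-array log-ratio data (and for anyone who wants a fully testable
reference implementation of this analysis), and it ships a synthetic-data
generator that emulates the study design with a planted ground truth, so
every stage is validated end to end.

## The statistic at the core

For one gene at one time point, let the per-chemical Z-normalised signed
significance scores (sign(mean difference) × log10(1/P) from a
pooled-variance *t*-test of treated vs matched control replicates) form a
male group and a female group of scalar points. Each point *x* receives a
silhouette index

    a(x) = mean |x − y| over the other same-sex points
    b(x) = mean |x − z| over the opposite-sex points
    s(x) = (b − a) / max(a, b)

and the Sex-Dependent Expression Score (SDES) is the mean of s over all
points. SDES ∈ [−1, 1]; values at or above 0.5 are called dimorphic.
Around this: Lowess MA-normalisation, Spearman/average-linkage profile
clustering with within/between-sex correlation-strength curves, a
permutation GSEA (weighted Kolmogorov–Smirnov running sum, gene-label
permutation null, same-sign NES, +1-corrected nominal p), and a pathway
network whose nodes scale with log10(1/p) and colour with NES. The methods
vignette (`vignettes/sdes-methods.Rmd`) documents every convention and
design choice.

## Worked example

```r
library(sdesr)

# a synthetic study: 4 chemicals x 2 sexes x 4 time points, 3 replicates,
# 10% of 320 genes planted as sex-dimorphic per time point
sim <- generate_dataset(synthetic_config(n_genes = 320, rng_seed = 42))
sim$dataset
#> expression_dataset: 320 genes x 120 samples (96 treated, 24 control)
#>   chemicals: CA, NP, As, Cd; times (h): 8, 24, 48, 96

cs <- condition_scores(filter_complete_genes(sim$dataset))
st <- sdes_table(cs, time_h = 24)
head(st, 3)
#>       gene time_h      sdes rank dimorphic
#> 1 gene0181     24 0.9466116    1      TRUE
#> 2 gene0118     24 0.9426590    2      TRUE
#> 3 gene0033     24 0.9380107    3      TRUE

calls <- classify_dimorphic(st)
truth_recovery_report(sim$truth, list("24" = calls$genes))
#>         time_h n_planted n_called true_positive false_positive sensitivity false_positive_rate
#> 24          24        32       61            32             29           1           0.1006944
#> overall     NA        32       61            32             29           1           0.1006944

rl   <- ranked_gene_list(setNames(st$sdes, st$gene))
sets <- synthetic_gene_sets(sim$truth, n_sets = 12, set_size = 15,
                            planted_ids = "planted_path", time_h = 24, seed = 43)
head(run_gsea(rl, sets, n_perm = 2000, seed = 7), 3)
#>         set_id size        es      nes    nominal_p n_perm
#> 1 planted_path   15 0.9508197 2.044142 0.0005136107   2000
#> 2        set06   15 0.5781057 1.245616 0.1497160558   2000
#> 3        set07   15 0.5650274 1.219549 0.1724315953   2000
```

Reading the numbers: all 32 planted genes are recovered (sensitivity 1.0)
and the gene set planted among the top-ranked genes is the clear GSEA
leader (NES 2.04, nominal p ≈ 5e-4). The 29 extra calls
(false-positive rate ~10%) are not a bug: with a shared control group per
sex, control-noise draws push all four chemicals of a sex coherently, and
the scale-invariant SDES scores such weak-but-consistent artifacts above
0.5 — a design-dependent false-positive floor that is measured, tested and
discussed in the methods vignette. The planted genes still rank far above
the artifacts, so the ranked lists feeding GSEA are robust.

`run_pipeline()` chains every stage (preprocessing → SDES per time point →
clustering → control-baseline ranking → GSEA → network) and writes all
outputs — score matrices, ranked SDES tables, Newick dendrograms,
correlation-strength curves, GSEA tables, GraphML networks, and a YAML
manifest with parameters and checksums — to a directory, bit-identically
under a fixed seed.

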