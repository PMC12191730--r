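# abmlm — preferential CDR3 masking for paired antibody language models

`abmlm` is an R toolkit for studying *region-weighted masking* in masked
language models (MLMs) of natively paired antibody sequences. Antibody
variable domains are mostly copied from germline V(D)J segments; almost all
of the interesting diversity sits in the CDR3 loops at the V(D)J junction.
A conventional MLM masks every residue with the same probability (15%), so
most of its training signal is spent on templated positions. Preferential
masking raises the CDR3 masking rate and rescales the rest so the average
stays fixed:

```
P(mask at x) = r_cdr3                                  if x in CDR3
             = (r_avg - r_cdr3 * p̂) / (1 - p̂)          otherwise
```

where `p̂` is the fraction of the pair's residues lying in either chain's
CDR3, `r_cdr3 = 0.25` and `r_avg = 0.15`. CDR3 positions then carry about
1.67× the training signal of a uniform model at identical overall
corruption.

The package is aimed at method developers who want the full mechanics of
this training scheme — simulator, tokenizer, masking plans, dynamic
80/10/10 collator, a compact rotary-attention encoder with exact manual
backprop, region-partitioned validation, per-position inference accuracy
with paired statistics, frozen-base pairing/specificity classifiers, and
gradient-based (AttCAT) token attribution — runnable end-to-end on a single
CPU with synthetic paired repertoires.

## What is in the box

| module | entry points |
|---|---|
| repertoire simulation | `sim_config()`, `build_germline_library()`, `simulate_repertoire()`, `implant_specificity()` |
| annotation & QC | `build_region_mask()`, `filter_dataset()`, `count_v_mutations()`, `cluster_identity()` |
| tokenizer | `build_vocab()`, `encode_pair()`, `decode_pair()`, `encode_dataset()` |
| masking | `preferential_probs()`, `uniform_probs()`, `build_plan_cache()`, `collate_batch()` |
| pre-training | `model_config()`, `count_parameters()`, `train_mlm()`, `validate_mlm()`, `select_checkpoint()` |
| evaluation | `per_position_accuracy()`, `compare_models()` |
| classifiers | `make_shuffled_pairs()`, `stratified_kfold()`, `train_head()`, `compute_metrics()`, `mutation_grid()` |
| attribution | `attcat_scores()`, `standardize()`, `region_enrichment()`, `select_explanation_cohort()` |
| pipeline / CLI | `abmlm_run()`, `run_pipeline()`, `inst/cli/abmlm.R` |

## Worked example

```r
library(abmlm)

vocab <- build_vocab()
reps  <- simulate_repertoire(sim_config(n_pairs = 200, seed = 1))
kept  <- filter_dataset(reps)$kept
ds    <- encode_dataset(kept, vocab)

plan <- preferential_probs(build_region_mask(kept[[1]], vocab))
round(c(p_hat = plan$p_hat_cdr3,
        cdr3 = 0.25,
        non_cdr3 = unique(plan$probs[plan$probs > 0 & plan$probs != 0.25]),
        mean = mean(plan$probs[plan$probs > 0])), 4)
#>    p_hat     cdr3 non_cdr3     mean
#>   0.0726   0.2500   0.1422   0.1500

cache <- build_plan_cache(ds, "preferential")
sched <- train_schedule("tiny", total_steps = 200, warmup_steps = 20,
                        checkpoint_interval = 100)
vmask <- make_validation_masks(ds, vocab, seed = 99)
run   <- train_mlm(ds, cache, model_config("tiny"), sched, vocab,
                   val_masks = vmask, seed = 0)
subset(run$trace, split == "val" & step == 200)
#>     step split  region     loss
#> 206  200   val overall 2.847402
#> 207  200   val    CDR1 2.825106
#> 208  200   val    CDR2 2.819024
#> 209  200   val    CDR3 2.860106
#> 210  200   val      FR 2.850194
```

The first block shows the masking arithmetic: this pair has 7.26% of its
residues in CDR3, so non-CDR3 positions are masked at 14.22% and the mean
over residue positions is exactly 15%. The second block is a 200-step tiny
training run; the validation loss is computed under fixed uniform masks and
partitioned into chain-agnostic region buckets — after this short run the
partly non-templated CDR3 bucket (2.860 nats) is already the hardest of the
four, the ordering that motivates weighting training signal toward it.

The full pipeline (simulate → pre-train under both strategies → region-wise
evaluation → pairing task → specificity task → attribution) is one call:

```r
run_pipeline("my_run", seed = 0)           # or: Rscript inst/cli/abmlm.R all --out my_run
```

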