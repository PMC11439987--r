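# texdistill

Scores per-sample **T-cell exhaustion** in bulk RNA-seq by transferring
exhaustion-stage labels from single-cell RNA-seq, and ranks the genes or
pathways that carry the signal.

Chronic antigen stimulation drives T cells through progenitor
(`TEXprog`), intermediate (`TEXint1`, `TEXint2`) and terminal (`TEXterm`,
PD-1-high) exhaustion states. These states are visible cell-by-cell in
scRNA-seq but mixed in unknown proportions in the bulk RNA-seq that most
clinical cohorts have. `texdistill` bridges the two modalities in two
stages:

1. **Teacher — domain adaptation.** Stage-labelled cells are averaged
   into *pseudo-bulk* blocks (weighted block sampling, majority-label
   assignment). A shared encoder with two heads is then trained jointly:
   an autoencoder reconstructs the real bulk matrix, a classifier
   predicts the pseudo-bulk stage labels, and a Gaussian-kernel **maximum
   mean discrepancy** (MMD) penalty pulls the two latent representations
   together,

   L = λ₂·‖X₁ − Ẑ₁‖²/N + λ₁·CE(Y₂ᵖʳᵉᵈ, Y₂) + λ₃·MMD²(Y₁, Y₂),

   with λ₁ = λ₂ = 0.1, λ₃ = 0.8, latent dimension 256, Adam at 1e-3, 100
   epochs, batch 100. The teacher's *soft label* for a bulk sample is its
   terminal-stage (TEXterm) classifier score.

2. **Student — sparse cross-modal distillation.** A one-hidden-layer
   network `sigmoid(relu(X₃W₁+b₁)W₂+b₂)` on a second modality (pathway
   activities or the full gene matrix) is trained to the soft labels with
   an L1 penalty (1e-4) on `W₁`; `B` bootstrap members are bagged and the
   ensemble mean is the exhaustion score. First-layer weight mass ranks
   exhaustion-associated features.

A synthetic-data generator with known terminal-exhaustion fractions, the
evaluation utilities (AUROC, AUPRC, median split, two-sample log-rank
test) and a held-out stage-identification benchmark are included, so the
whole pipeline is testable without any data download. All networks and
gradients are written directly in (BLAS-backed) matrix algebra — there is
no autodiff dependency.

See the methods vignette (`vignettes/texdistill-methods.Rmd`) for the
model, its assumptions, and every design decision.

## Worked example

Simulated reference with planted stage markers; every number below is the
script's actual output.

```r
library(texdistill)

cfg <- sim_config(n_genes = 1000, cells_per_stage = 400,
                  markers_per_stage = 40, n_bulk = 200)
sim  <- simulate_cells(cfg, seed = 42)
norm <- normalize_cells(sim$cells)
hvg  <- select_hvg(norm, 500)
norm <- expr_mat(norm$values[, hvg], "lognorm")

pb <- sample_blocks(norm, sim$labels, block_size = 100, n_blocks = 400,
                    target_weight = 10, seed = 42)
pb
#> <pseudobulk_set> 400 blocks x 500 genes, block size 100, target weight 10
#> TEXprog TEXint1 TEXint2 TEXterm   other
#>      80      80      80      80      80

bs <- simulate_bulk(sim$truth, cfg, seed = 42)
be <- expand_bulk(expr_mat(bs$bulk$values[, hvg], "counts"), 400, seed = 42)
teacher <- train_teacher(pb, be, loss_config(),
                         train_config(epochs = 60, seed = 42))
teacher
#> <tex_teacher> 500 genes -> latent 256 -> 5 stages (terminal: TEXterm)
#>   final losses: reconstruction 0.672, category 0.001774, mmd 0.006063

soft <- teacher_soft_labels(bs$bulk, teacher)
round(head(soft, 4), 3)
#> b0001 b0002 b0003 b0004
#> 0.031 0.002 0.652 0.001
cor(soft, bs$texterm_fraction, method = "spearman")
#> [1] 0.9338108
```

The soft labels already track each sample's true terminal-exhaustion
fraction (Spearman 0.93). Distilling into the sparse student ensemble on
the gene matrix sharpens the ranking and exposes the drivers:

```r
X3  <- expr_mat(log2(1 + bs$bulk$values[, hvg]), "log2")
ens <- train_student(X3, soft, d_hidden = 64, epochs = 300, B = 5,
                     seed = 42)
score <- ensemble_score(X3, ens)
cor(score, bs$texterm_fraction, method = "spearman")
#> [1] 0.9759619

head(feature_importance(ens), 3)
#>   feature_id importance rank
#> 1      g0137  0.3848275    1
#> 2      g0125  0.3791568    2
#> 3      g0144  0.3764942    3
```

The three top-ranked genes all lie in the planted TEXterm marker block
(`g0121`–`g0160`). Downstream, scores split a cohort for survival
comparison:

```r
surv <- simulate_survival(bs$texterm_fraction, hazard_ratio = 4, seed = 42)
res <- log_rank(median_split(score), surv)
c(chi_square = res$chi_square, p = res$p_value)
#> chi_square          p
#> 3.67843219 0.05512066
```

(borderline at n = 200 — the simulated hazard ratio of 4 applies across
the whole fraction range, and a median split only contrasts part of it).

## Command line

A thin CLI over the same functions ships in `inst/cli/`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/texdistill.R", package="texdistill"))')
Rscript $CLI simulate  --out sim/ --seed 1
Rscript $CLI pseudobulk --cells sim/cells.mtx --labels sim/labels.tsv \
        --block-size 100 --n-blocks 1000 --weight 10 --seed 1 --out pb/
Rscript $CLI train-teacher --pseudo pb/ --bulk sim/bulk.csv --out teacher/
Rscript $CLI distill --bulk sim/bulk.csv --teacher teacher/ --genes --out student/
Rscript $CLI score   --student student/ --input sim/bulk.csv --log2 --out scores.tsv
Rscript $CLI evaluate --scores scores.tsv --survival sim/survival.tsv --out eval/
```

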