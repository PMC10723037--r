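# bindgraph

Residue-level prediction of peptide- and protein-binding sites from protein
structures with an edge-aware Graph Transformer.

## What it does, and for whom

Given a protein structure (a predicted model is fine — only the backbone is
used) and a per-residue embedding matrix from a protein language model,
`bindgraph` assigns every residue a probability of belonging to a binding
interface. It is aimed at structural bioinformaticians who want a
self-contained, inspectable R implementation of the full pipeline:
invariant geometric featurization, the graph neural network itself,
the cross-validated training protocol, and imbalance-aware evaluation —
plus a synthetic-fixture generator so everything runs at desk scale with
no downloads.

## The model

A protein with n residues becomes a directed graph: node i sits at its
Cα coordinate **x**ᵢ and connects to its k = 30 nearest residues plus a
self-loop. Node features are the concatenation of a min–max-normalised
language-model embedding block and a 14-dimensional structural block
(RSA, 9-column secondary-structure one-hot, torsion sin/cos). Each edge
i → j carries rotation- and translation-invariant features

> e⁽ˢ⁾ᵢⱼ = [ rbf(‖xⱼ − xᵢ‖) ‖ Oᵢᵀ(xⱼ − xᵢ)/‖xⱼ − xᵢ‖ ‖ q(OᵢᵀOⱼ) ]

(16 Gaussian RBFs on [0, 20] Å, the neighbour direction in residue i's
local backbone frame Oᵢ, and the quaternion of the relative frame
rotation), concatenated with a sinusoidal encoding of the signed sequence
gap j − i. A 4-layer, 4-head, 64-unit Graph Transformer updates node i by
attending over its neighbourhood with edge-conditioned keys and values,

> αᵢⱼ = softmaxⱼ ( (W_Q hᵢ)ᵀ W_K [hⱼ ‖ eᵢⱼ] / √d_h ),  
> hᵢ′ = hᵢ + Σⱼ αᵢⱼ W_V [hⱼ ‖ eᵢⱼ],

and a sigmoid head yields per-residue probabilities, Y′ = σ(H_L W + b).
Training minimises residue-level binary cross-entropy with Adam
(β₁ = 0.9, β₂ = 0.98, ε = 1e-9), Gaussian feature-noise augmentation,
early stopping on validation AUPRC, and protein-level 5-fold
cross-validation; the five fold models are ensembled by averaging, and the
decision threshold maximises MCC on validation predictions. Forward and
backward passes are hand-vectorised base R, validated by finite
differences.

## Worked example

Fit a small ensemble on synthetic fixtures whose labels follow spatial
hotspots while the embeddings only describe sequence neighbourhoods — the
regime where graph message passing is actually needed:

```r
library(bindgraph)

ds <- make_dataset(synthetic_spec(n_proteins = 10, length_range = c(30, 45),
                                  pn_ratio_target = 0.18, embed_dim = 8,
                                  signal_mode = "structure_only", seed = 42))
ds
#> bindgraph_dataset: 10 proteins, 397 residues, PN ratio 0.157

fit <- bindgraph_fit(ds,
  model = bindgraph_config(num_layers = 2, num_heads = 2, hidden_dim = 16,
                           seed = 42),
  training = train_config(proteins_per_epoch = 8, batch_size = 4,
                          max_epochs = 4, patience = 4, n_folds = 5,
                          seed = 42),
  k = 8, pos_dim = 8)
fit
#> Edge-aware Graph Transformer binding-site ensemble
#>   5 fold members | 2 layers, 2 heads, d=16 | k=8
#>   decision threshold (median max-MCC over folds): 0.0815

scores <- predict(fit, ds)
round(scores$SYN001[1:5], 3)
#> 0.048 0.064 0.035 0.072 0.072

y <- unlist(lapply(ds$records, function(r) r$labels))
evaluate_predictions(y, unlist(scores), threshold = fit$threshold)
#> TP=20 TN=320 FP=23 FN=34 (threshold 0.0815)
#> ACC=0.8564 Pre=0.4651 Rec=0.3704 Spe=0.9329 F1=0.4124 MCC=0.3346
#> AUC=0.6724 AUPRC=0.3593
```

The PN ratio line reports the realised positive/negative imbalance of the
planted labels (targeting the protein-like 0.18 regime). The threshold is
the median of the per-fold MCC-maximising values, and the final report
gives confusion counts with the six threshold metrics plus
threshold-independent AUC/AUPRC. In-sample numbers after four epochs of a
deliberately tiny model are modest by design — the point of the example is
the mechanics, not the score; `vignettes/binding-site-prediction.Rmd`
explains the model, the protocol and every tunable in detail.

Real structures enter through `read_structure("file.pdb", chain = "A")`,
DSSP annotations through `secondary_structure_onehot()`, and a shell
workflow (`train` / `predict` / `evaluate` / `make-fixtures`, YAML-driven)
through the installed `exec/bindgraph` script or the exported `cmd_*()`
functions.

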