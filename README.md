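# resibind

Per-residue prediction of protein–DNA binding sites from sequence
embeddings, for structural bioinformaticians who need residue-level binding
annotations when no complex structure is available — and a fully offline,
seeded synthetic benchmark for exercising every stage of such a pipeline.

## What it computes

Given per-residue embeddings $X \in \mathbb{R}^{L \times D}$ of a protein
of length $L$ (from a frozen ProtBert-style language model, or from the
package's deterministic fallback embedder), a four-layer 1-D convolutional
network with stride 1 and same-length padding maps $X$ to per-residue
class probabilities through a softmax head. Training minimizes

$$ L \;=\; \underbrace{\tfrac1M \sum_i \tfrac{1-\beta}{1-\beta^{\,n_{y_i}}}
   (1-p_i)^{\gamma} \bigl(-\log p_i\bigr)}_{\text{class-balanced focal loss}}
   \;+\; \lambda\, \underbrace{\tfrac1M \sum_i
   \max\bigl(D(f_i, c_{y_i}) + m - D(f_i, c_{\bar y_i}),\, 0\bigr)}_{\text{triplet center loss}} $$

with $D(f,c)=\tfrac12\lVert f-c\rVert_2^2$, learnable class centers $c_y$,
and defaults $\beta = 0.999$, $\gamma = 5$, $\lambda = 0.1$, $m = 9$,
center learning rate 0.01. The effective-number weight
$(1-\beta)/(1-\beta^{n_y})$ counteracts the ~5–9% positive-residue rate of
binding-site data; the focal modulator focuses training on hard residues;
the contrastive term shapes a feature space with one tight cluster per
class. Evaluation reports specificity, precision, recall, F1, MCC, ROC/PR
curves with AUC and AUPR, amino-acid composition profiles and KL
divergences. Ground-truth labels can be derived from protein–nucleic-acid
complex structures by the van der Waals rule: a residue is binding when
any heavy-atom pair (residue atom, nucleic-acid atom) is closer than the
sum of the two van der Waals radii plus 0.5 Å.

## Worked example

```r
library(resibind)

syn <- generate_synthetic(synthetic_spec(n_sequences = 40, seed = 7))
fit <- train_binding_model(syn$dataset, syn$embeddings,
                           backbone_cfg = backbone_config(input_dim = 16),
                           train_cfg = train_config(epochs = 25, seed = 7))
preds <- predict_binding(fit, syn$embeddings)
evaluate_predictions(preds, syn$dataset$labels)
#> metrics_report @ threshold 0.50
#>   Spe 0.865  Pre 0.281  Rec 0.912  F1 0.429  MCC 0.462
#>   AUC 0.952  AUPR 0.816
```

Read as: on its own (deliberately easy, in-sample) training data the model
recovers 91% of binding residues at the default 0.5 cutoff; precision is
modest because the class-balanced loss is tuned to favor recall on
~6%-positive data (an MCC of 0.46). Threshold-free ranking quality is AUC
0.952, AUPR 0.816. The
full-size reference experiment — 200 sequences, 20% held out, class
separation 2 — is `synthetic_benchmark(seed = 0)` and reaches
held-out AUC ≥ 0.95; with `separation = 0` (embeddings carry no label
information) it stays at chance.

Labeling from a structure and a shell session:

```r
res <- label_binding_sites(read_structure("complex.pdb"))
res$A$labels   # 0/1 per residue of chain A, sequence order
```

```sh
Rscript inst/cli/resibind.R simulate --spec spec.yaml --out data/
Rscript inst/cli/resibind.R train --fasta data/sequences.fasta \
    --labels data/labels.txt --embeddings data/embeddings.rds --out run/
Rscript inst/cli/resibind.R --help
```

## Layout

| Path | Contents |
| --- | --- |
| `R/sequence_io.R` | FASTA + label-track I/O, dataset pairing and stats |
| `R/embedding.R` | embedder contract, ProtBert adapter, fallback, cache |
| `R/backbone.R` | 1-D CNN forward/backward, masking, batch norm |
| `R/losses.R` | effective number, focal loss, TCL, joint objective |
| `R/trainer.R` | Adam + center SGD, early stopping, checkpoints |
| `R/metrics.R` | confusion metrics, ROC/PR, composition, KL |
| `R/synthetic.R` | seeded run-length + Gaussian-cluster generator |
| `R/site_labeling.R` | structure parsing, vdW-rule labeling |
| `R/pipeline.R` | config-driven end-to-end runs, reference benchmark |
| `inst/cli/resibind.R` | command-line wrapper (simulate/embed/train/...) |
| `vignettes/` | methods vignette: model, assumptions, design choices |
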