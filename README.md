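# sebiograph

Few-shot semi-supervised learning on banks of biomedical graphs, with
knowledge transfer from auxiliary graphs to a sparsely labeled target graph.

Biomedical networks — protein–protein interaction maps, drug–drug interaction
graphs, clinical term co-occurrence graphs — rarely come with abundant node
labels: annotation is expensive, so a typical graph offers a handful of
labeled nodes per class. `sebiograph` addresses node classification and link
prediction in this regime by meta-training a metric space over a *bank* of
related graphs, so that prototypes built from a few labeled nodes of a new
target graph already separate its classes.

## Model

Each graph is `G = (A, N)` with binary symmetric adjacency `A ∈ {0,1}^{m×m}`
and node features `N ∈ R^{m×h}`. The building blocks, trained jointly:

- **Encoder** `f_θ`: a two-layer graph convolution (self-loops added,
  symmetric degree normalization `Â = D̃^{-1/2}(A+I)D̃^{-1/2}`, rectifier
  between layers, 32 units per layer) mapping nodes to a shared metric space.
- **Hierarchical representation gate**: per graph, a softmax assignment GNN
  soft-clusters nodes (`P` row-stochastic), the graph is coarsened
  (`A' = PᵀAP`, `N' = Pᵀ·FGNN(A,N)`), each level is max-pooled to a vector,
  the levels are combined by attention against a learnable query, and a
  sigmoid map produces a gate `g ∈ (0,1)^32` that rescales the globally
  shared output-layer block `α` row-wise (`α_i = g_i ∘ α`). Similar graphs
  thus share nearby metric spaces while each graph gets its own modulation.
- **Structured prototypes**: for each class in an episode's support set, an
  intra-class relation graph weights pairs of support nodes by inverse
  shortest-path distance plus shared k-hop neighborhood overlap; a one-layer
  graph convolution over this relation graph followed by coordinate-wise max
  pooling yields the class prototype `c^k`.
- **Episode loss**: queries are scored by a distance softmax over prototypes,
  `L = -Σ log softmax_k(-d(f(n), c^k))` (squared Euclidean by default).
- **Auxiliary reconstruction**: a one-layer decoder GNN gives `Z`, and
  `L_d = ‖A - ZZᵀ‖_F²` regularizes embedding quality; the joint objective per
  episode is `L + β·L_d`, minimized by gradient descent (or Adam) with
  analytic gradients from the package's internal reverse-mode tape.

At evaluation the meta-learned parameters are frozen; prototypes are built
from the target's small support set and the remaining labeled nodes are
classified (micro/macro F1). Link prediction embeds a candidate pair as the
coordinate-wise product of its endpoint embeddings and applies the same
prototype classifier to edges vs sampled non-edges on an 80/20 split.

## Worked example

```r
library(sebiograph)

bank <- generate_bank(sim_preset("easy"), seed = 1)  # 5 auxiliary + 1 target
bank
#> <graph_bank> 6 graphs (5 auxiliary, 1 target)
bank$graphs[[1]]
#> <bio_graph> 200 nodes, 888 undirected edges, 16 features, 60 labeled

fit <- sebiograph(bank, sebiograph_config(optimizer = "adam",
                                          episodes_per_epoch = 200, seed = 1))
fit
#> Few-shot graph model (gated GCN encoder + structured prototypes)
#>   episodes trained : 200
#>   hidden/out width : 32/32, hierarchy depth 2
#>   final loss       : 0.0040 (episode 0.0000 + beta*recon)

target <- bank$graphs[[which(bank$roles == "target")]]
ev <- evaluate_node_classification(fit, target, shots = 10, seed = 1)
c(ev$micro_f1, ev$macro_f1)
#> [1] 1 1
evaluate_link_prediction(fit, target, shots = 10, folds = 5, seed = 1)$accuracy
#> [1] 0.7867925
```

The training loss falls from 0.567 (mean of the first 20 episodes) to 0.004
(last 20); with class means 5σ apart the frozen model then classifies every
held-out target node correctly from 10 labeled examples per class, and
separates true edges from sampled non-edges well above the 0.5 chance level.

A command-line interface wrapping the same functions is installed at
`inst/cli/sebiograph.R` (`simulate`, `train`, `eval`, `embed` subcommands).

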