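---
title: "Designing sequences for target secondary structures with reduced amino acid alphabets"
author: "ssdesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing sequences for target secondary structures with reduced amino acid alphabets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssdesign)
```

## The problem

Given a target secondary structure — a per-residue DSSP string over the nine
states H (α-helix), G (3₁₀-helix), I (π-helix), E (β-strand), B (bridge),
T (turn), S (bend), P (polyproline II), C (coil) — and a *reduced amino acid
alphabet* (a subset of the 20 canonical residues), the package generates an
amino acid sequence predicted to adopt that structure using only residues
from the alphabet. The scientific motivation is coverage theory: the
canonical alphabet spans size, hydrophobicity and charge non-randomly, and a
model grounded in those physicochemical descriptors rather than in residue
identity alone should, in principle, design within any sub-alphabet — and
eventually within xeno-alphabets for which no sequence data exist.

The model is conditioned on two tracks derived from the target: the 9-state
DSSP string and its collapsed 3-class type track (helix = {H, G, I},
sheet = {E, B}, coil = {T, S, P, C}). Polyproline II is assigned to coil;
the three published classes do not name it, and PPII geometry is closest to
an extended coil, so this is the package's reading. Inputs `-`, space and
`~` are accepted as coil synonyms (mkdssp conventions).

## Physicochemical grounding

Each residue carries a fixed descriptor triple at pH 7.0: van der Waals
volume (Å³), octanol/water logD, and formal charge. The triples are package
constants (`residuePropertyTable()`); they were computed originally with a
commercial calculator and are looked up, never recomputed. The model
regresses these triples per position alongside classifying the residue, so
the learned representation is anchored in the physics rather than only in
the 20-way label. Because the raw scales differ by two orders of magnitude
(volumes ~70–180, charges ∈ {−1, 0, 1}), the regression targets are
z-scored per property using statistics of the *training split only*; the
standardizer is stored with the model checkpoint and in its JSON sidecar.

## Alphabet libraries

An `Alphabet` is a subset of the canonical 20 with a reduction-method label;
its canonical form is the sorted member string (`"ACDE"`). Libraries are
CSV files (`method`, `alphabet`, optional `id`); grouping notation such as
`"LVIM-AG-ST"` can be unioned with `groups = TRUE`, since published
reduction tables sometimes list partitions rather than member sets.
`filterAndSample()` reproduces the published curation: drop alphabets of
size 5 or smaller, group by (size, method), and keep one random alphabet per
group. Group iteration is lexicographic on (size, method) and draws come
from one seeded stream, so the selection is platform-stable. Descriptive
statistics follow the published summaries: `sizeStatistics()` (sample
standard deviation, n − 1 denominator; a single-alphabet library reports
sd 0 with a degeneracy warning), `compositionFrequencies()` (fraction of
alphabets containing each residue — the per-alphabet membership reading; a
letters-share variant is exposed as an option), and `cooccurrenceMatrix()`.

## The network

`modelConfig()` defaults reproduce the published architecture:

* 64-dimensional embedding of the 9 DSSP states, concatenated with a
  16-dimensional embedding of the 3 type classes → an 80-dimensional
  combined input;
* three bidirectional LSTM layers with 256 hidden features per direction
  (512-wide output);
* layer normalization of the encoder output, then 8-head self-attention
  over the 512-wide sequence with a residual connection;
* a decoder of two (linear → ReLU → dropout) stages;
* a 20-way residue classifier head and a 3-way property regression head,
  both per position.

Three points were genuinely open and are resolved as follows.

**The "context vector" is length-preserving.** The classifier must emit
logits at every position, so the attended sequence (not a pooled vector) is
what enters the decoder.

**Attention placement.** The published description lists "layer
normalization and 8-head multi-head attention" without an order; the package
normalizes the LSTM stack output first, applies self-attention to the
normalized sequence, and adds a residual connection. Padded positions are
excluded from attention by key masking, and the masked LSTM carries hidden
state through padded steps unchanged, so padding can never leak into real
positions (this is tested by comparing outputs under different pad lengths).

**Decoder widths.** The published text fixes every dimension except the two
decoder widths, but prints the total trainable parameter count, 5,065,280.
The widths were resolved by exhaustive search over the parameter inventory
(embeddings with one padding row each, per-direction LSTM blocks with the
usual two bias vectors, one layer-norm affine pair, packed-QKV and output
attention projections with biases, two decoder stages, two heads). The
search over d1, d2 and the discrete variants (number of layer norms,
attention biases, padding rows) admits a small number of arithmetic
solutions; the only family consistent with the described architecture
(layer normalization present, biased attention projections, padding rows
for padded batching) gives **512 → 279 → 78**, which reproduces the count
exactly:

```{r params}
cfg <- modelConfig()
parameterCountFromConfig(cfg)
combinedInputDim(cfg)
```

`countParameters(buildModel(cfg))` agrees with the closed form; the test
suite verifies the identity on several toy configurations as well. The
classifier output layer is initialized Xavier-uniform with gain 0.1 and
zero bias; other layers use conventional defaults (uniform ±1/√fan for LSTM
and linear stages, Xavier for attention projections, standard normal
embeddings with a zero padding row).

## The loss

For a batch with validity mask M (padded positions contribute to *no*
component):

total = α·MSE + β·CE(T) + γ·(−H̄) + λ·mean(logits²)

with α = 1.0 (property mean-squared error over unmasked positions and the
3 standardized properties), β = 0.2 (cross-entropy on logits divided by the
annealed temperature T, against the ground-truth residues), γ = 0.01
(entropy regularization), and λ = 10⁻⁴ (an L2 penalty on logits; the
published text names the penalty but not its weight, so λ is configurable).
Two sign/scope conventions are the package's own: the entropy term *adds*
−γ·mean(entropy), i.e. entropy is encouraged, consistent with an
exploratory-to-exploitative temperature narrative (a sign switch is
exposed); and the prediction entropy is computed on the same
temperature-scaled softmax as the cross-entropy. "Teacher forcing" is read
as standard per-position cross-entropy against ground-truth labels: the
decoder is feedforward and non-autoregressive, so there is no
previous-token feed to force.

Every backward pass is hand-derived (there is no autodiff here); the test
suite checks all analytic gradients against central finite differences on a
ragged masked batch, and checks that gradient reaches every trainable
tensor.

## Training

`trainingConfig()` defaults: 50 epochs, batch size 8, AdamW (learning rate
10⁻³, decoupled weight decay 0.01), cosine annealing warm restarts with
first period T = 20 and period doubling (T_mult = 2), temperature annealed
linearly from 2.0 at epoch 0 to 0.5 at the final epoch, gradient clipping
at global norm 1.0. The scheduler steps per *epoch*: the published T = 20
is commensurate with 50 epochs, which makes the restart fall at epoch 20
and the second cycle span 40 epochs. Validation loss is computed with
dropout off at temperature 1 so epochs are comparable; the checkpoint with
minimum validation total loss is retained (published text does not say
final-vs-best; best is this package's choice). Training aborts with a
diagnostic naming the first non-finite loss component.

All randomness flows from one root seed split into named streams
(`deriveSeed(seed, stream)`) for splitting, initialization, shuffling,
dropout and sampling, so runs are bitwise reproducible and components can
be reproduced independently. A `mixed_precision` flag is accepted for
configuration compatibility; R computes in double precision, so the flag
reports that and proceeds in double — reproducibility is unaffected.

## Inference

At design time the model emits logits over all 20 residues at each
position; logits of residues outside the requested alphabet are set to the
most negative finite double before the softmax. The finite stand-in for
−∞ avoids NaN propagation; what is contractual (and tested over ten
thousand fuzzed pairs) is the post-softmax behaviour: exactly zero mass
outside the alphabet, renormalized mass inside it. Greedy decoding takes
the positionwise argmax; exact ties break to the alphabetically first
residue so decoding is deterministic. Batch design runs one encoder forward
per target and reuses it across alphabets, which is output-identical to
re-running per alphabet for a deterministic model. A target whose length
falls outside the trained length envelope triggers a warning, not an error.

## Evaluation metrics

* **Percent identity (PID).** Equal lengths (the designed-sequence case by
  construction): 100 × matching positions / length. Unequal lengths:
  end-to-end global alignment with match +1, mismatch 0, gap −1 via
  `Biostrings::pairwiseAlignment`, PID = 100 × matches / alignment length.
  The alignment package is the published choice; the parameters are not, so
  they sit in one place and the test suite pins them against an independent
  dynamic-programming oracle.
* **Complexity.** Shannon entropy of the observed state frequencies divided
  by ln 9; transition frequency (state changes / (length − 1)); Simpson
  diversity 1 − Σp². The composite is their equally weighted mean. The
  transition metric counts changes over the **9-state** tokens — the
  published wording ("secondary structure type changes") could mean the
  3-class track, but the other two components are 9-state quantities, so
  9-state is the default and the 3-class variant is an option.
* **Tertile binning.** low/medium/high at the empirical 1/3 and 2/3
  quantiles, ties resolved by stable rank (class sizes differ by at most 1
  for distinct scores); an all-identical vector collapses to "low" with a
  warning. Labels are invariant under order-preserving transforms.

## The synthetic generator, and what passing tests mean

`sampleDssp()` draws run-length-structured strings: a class from the class
weights, a geometric run length with the class mean (memoryless — one
parameter per class, the simplest model that produces realistic run
structure), states within the run from the within-class weights, total
length uniform in [10, 300] (the curation bounds). `ruleMap()` attaches a
known DSSP-state → residue rule; the default is property-consistent (helix
states prefer A/L/E/K, sheet V/I/F/Y, coil G/P/S/N) so the property head
receives a learnable physicochemical signal. Position draws emit the modal
residue with probability 1 − noise and otherwise sample the state's full
distribution, so noise 0 is exactly the modal map.

The generator emulates the *shape* of curated structural data — segment
structure, length bounds, a learnable sequence–structure relationship. It
deliberately does not emulate true secondary-structure statistics,
long-range tertiary constraints, or homology redundancy. Passing the
recovery benchmark therefore demonstrates that the architecture, loss,
optimization and constrained decoding are implemented coherently end to
end; it does not certify design accuracy on real proteins, which in the
published work required folding-engine validation at corpus scale.

## The recovery benchmark

`recoveryBenchmark()` is the package's core self-test: a noiseless rule
whose modal residues lie inside the 6-member alphabet AGLPSV, a reduced
model (~50K parameters: 16 + 8 embeddings, three biLSTM layers of 24,
8-head attention, decoder 48 → 24 → 12), 320 examples of length 10–60 with
uniform within-class state weights (so all nine states are well represented
at this scale — the skewed default weights leave G/I/B/S too rare to learn
from a few hundred short sequences), 10 epochs, and 10 freshly sampled
held-out targets. Greedy designs under the alphabet are scored against the
modal rule sequences; the acceptance bar is mean PID ≥ 95% for at least 2
of 3 seeds. These problem sizes are the package's chosen benchmark scale:
small enough to run routinely on one CPU, large enough that every
architectural component participates.

## Known limitations

* The published corpus-scale benchmarks (mean PID by alphabet size and
  complexity class, pTM/TM-score/RMSD validation, the design-success
  classifier) require the full PDB-derived corpus, GPU folding engines and
  experimental structures; they are out of scope here, and the package's
  evaluation module instead consumes externally produced secondary-structure
  predictions.
* DSSP assignment from 3-D coordinates and sequence clustering are external
  tools; the dataset module consumes their outputs (cluster labels,
  representative flags).
* Training is single-device and double-precision; the published wall-clock
  (2 h for 50 epochs) assumed GPU mixed precision and does not transfer.
* The property table is fixed at pH 7.0 and covers the canonical 20 only;
  xeno-alphabet tables would be drop-in but are not shipped.
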