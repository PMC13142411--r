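# ssdesign

Secondary-structure-conditioned protein sequence design with reduced amino
acid alphabets.

## What it does, and for whom

Given a target secondary structure — a DSSP string over the nine states
H/G/I (helices), E/B (sheet/bridge), T/S/P/C (turn/bend/polyproline/coil) —
and a subset of the 20 canonical residues (a *reduced amino acid alphabet*),
`ssdesign` generates an amino acid sequence predicted to adopt that
structure using only residues from the alphabet. It is aimed at protein
designers, synthetic biologists and origin-of-life researchers who want to
ask: *which structural motifs remain designable as the alphabet shrinks?*

The core is a bidirectional LSTM encoder–decoder with multi-head
self-attention, trained on paired (DSSP, sequence) data plus per-residue
physicochemical descriptors (van der Waals volume, logD at pH 7, formal
charge). Per position *i* with encoder context **h**<sub>i</sub>, the model
emits residue logits **z**<sub>i</sub> ∈ ℝ²⁰ and a property triple
**ŷ**<sub>i</sub> ∈ ℝ³, trained with the composite loss

&nbsp;&nbsp;&nbsp;&nbsp;L = α·MSE(ŷ, y) + β·CE(z/T, r) + γ·(−H̄(softmax(z/T))) + λ·mean(z²)

with α = 1.0, β = 0.2, γ = 0.01, temperature T annealed linearly 2.0 → 0.5,
AdamW (lr 10⁻³, weight decay 0.01) under cosine-annealing warm restarts
(T = 20, T_mult = 2), and gradient clipping at norm 1.0. The default
configuration (64 + 16 embeddings → 80-dim input, 3 × biLSTM(256),
layer norm, 8-head attention, decoder 512 → 279 → 78) has exactly
**5,065,280** trainable parameters. At inference, logits of residues
outside the requested alphabet are masked to −∞ before the softmax, so
designs are *guaranteed* to stay inside the alphabet; decoding is greedy
(positionwise argmax, alphabetical tie-break).

Around the model sit the full supporting pipeline: alphabet-library
curation (stratified sampling by size × method after dropping size ≤ 5),
dataset curation (length 10–300, cluster-representative filtering), 70/20/10
splits and padded batching, DSSP complexity metrics (normalized Shannon
entropy, transition frequency, Simpson diversity, and their composite with
tertile binning), percent-identity evaluation, and a seeded synthetic-data
generator so everything is testable offline. The whole network — forward
and backward passes — is implemented in R and verified against
finite-difference gradients in the test suite.

## Worked example

Train the reduced self-test model on a noiseless synthetic rule (DSSP state
→ residue inside the 6-letter alphabet AGLPSV), then design:

```r
library(ssdesign)

bench <- recoveryBenchmark(seed = 1)   # ~1 min on one CPU
round(bench$mean_pid, 1)
#> [1] 100

target <- "CCHHHHHHHHHHTTTTEEEEEEESSCC"
designSequence(bench$model, target, Alphabet("AGLPSV", method = "recovery"),
               target_id = "demo")
#> DesignResult demo|recovery:AGLPSV: GGLLLLLLLLLLGGGGVVVVVVVSSGG

round(unlist(compositeComplexity(target)), 3)
#>    shannon transition    simpson  composite
#>      0.672      0.192      0.746      0.537

percentIdentity("HHHH", "HHEE")
#> [1] 50
```

`bench$mean_pid` is the mean percent identity of greedy designs against the
modal rule sequences on 10 held-out targets — 100 means the trained model
recovered the generating rule exactly. The designed sequence follows the
rule positionwise (helix → L, strand → V, turn/coil → G, bend → S) while
using only alphabet members. The complexity components score the target's
state diversity, change rate and evenness on [0, 1]; their mean is the
composite used for low/medium/high binning.

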