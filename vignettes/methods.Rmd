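---
title: "Methods: structured reporting and dual-stream fusion classification for breast MRI reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structured reporting and dual-stream fusion classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A breast MRI report is a free-text narrative written by a radiologist. Two
readers describing the same lesion will distribute the same findings across
different sentences, in different orders, with different emphasis. For
computer-aided triage — distinguishing lesions that warrant biopsy (BI-RADS
4A–6) from those that warrant follow-up (BI-RADS 1–3) — that variability is
noise. Structured reporting removes it: the narrative is recast into a fixed
ten-category template (fibroglandular tissue amount, background parenchymal
enhancement, mass/non-mass, axillary lymph nodes, skin lesions, non-enhancing
findings, associated findings, fat-containing lesions, DCE curve assessment,
prosthesis), one descriptor per category.

`biradsfusion` implements a desk-scale version of that pipeline end to end:

1. **Structuring.** A deterministic reference structurer
   (`parse_free_text()`) plays the role of an LLM backend for the package's
   synthetic report dialect; the prompt-assembly module defines the contract
   a real LLM backend would fill (`register_llm_backend()`), including
   knowledge-driven prompts that embed per-category lexicon definitions.
2. **Missing-category completion (MCI).** Categories the narrative never
   mentions are filled with the exact sentinel `"not mentioned"`
   (`complete_mci()`), so every structured report has all ten slots. The
   absence of a finding is itself information; the sentinel makes it visible
   to a learner.
3. **Classification.** Two from-scratch transformer encoders — one per
   stream (free text, structured template text) — feed one of five fusion
   strategies and a softmax head (`birads_fit()`). Attention projections are
   LoRA-parameterized: a frozen base matrix plus a trainable low-rank update.
4. **Evaluation.** BERTScore over contextual embeddings grades structuring
   quality; precision/recall/F1/AUC grade classification; a seeded ablation
   harness (`run_ablation()`) reruns the MCI / personal-history / fusion
   contrasts.

No clinical data ships with the package. The synthetic generator
(`generate_corpus()`) defines the study conditions, and everything the tests
claim is claimed about those conditions.

## The synthetic corpus

Each record draws one descriptor per category uniformly from the lexicon. A
logistic label model turns descriptors into a biopsy probability:

$$P(\text{biopsy}) = \mathrm{logit}^{-1}\Big(\beta_0 + \sum_f \beta_f\,
\mathbb{1}[f\ \text{active}]\Big)$$

with features for washout kinetics (1.6), irregular (1.2) and spiculated
(1.8) mass margins, suspicious axillary nodes (1.2), skin thickening (0.6),
and a malignant-leaning personal-history clause (1.0); the intercept −0.9
puts the biopsy prevalence near 0.70, in the neighbourhood of the ~0.75
prevalence typical of a biopsy-enriched referral cohort. These weights are
fixed defaults (`default_beta()`), not tuning knobs: they were chosen once,
before any classifier existed, as the simplest process in which
biopsy-leaning descriptors carry recoverable signal. The trainability
benchmark replaces them with a single extreme weight (washout 60, intercept
−30), which makes the label a deterministic function of one descriptor;
that benchmark trains with max pooling — detecting the presence of one
token is precisely what max pooling over the sequence axis computes — at
learning rate 0.2, batch 16.

**Missingness.** Each category is omitted from the narrative with base
probability 0.3. Under the default `informative` mode, the omission
probability of a category whose latent descriptor is biopsy-leaning is
multiplied by 0.25 — malignant findings are rarely left out of a report — so
the missingness *pattern* correlates with the label. That is precisely the
signal MCI completion exposes: with the sentinel present, a model can read
"axillary nodes not mentioned" as weak evidence of benignity. Under `MCAR`
the modulation is off and missingness carries no signal (the test suite
verifies both, via a permutation test on a plug-in mutual-information
estimate).

**Personal history.** With probability 0.4 a PH clause is appended, drawn
from a malignant-leaning family ("post-surgery for prior carcinoma…") or a
benign family ("routine screening follow-up") with equal probability; the
malignant family is a label-model feature. The structured template has no PH
slot, so this signal exists only in the free-text stream — the basis of the
PH ablation.

**Surface variation.** Each mentioned category is realized as one sentence
from ≥3 surface templates (seeded choice), so a classifier cannot memorize a
single sentence frame. Template wording avoids every lexicon term, which
gives the reference structurer an exact round-trip guarantee on this
dialect: `complete_mci(parse_free_text(text))` equals the generator's ground
truth, string for string. Real clinical narratives offer no such guarantee —
passing round-trip tests here says the plumbing is lossless, not that the
parser generalizes to hospital text.

**Splits.** 70/20/10 train/test/validation with floor-on-val-and-test and
the remainder to train: the only deterministic rule that reproduces
8320/2376/1188 on 11,884 records. Splits are unstratified (a stratified
option is not provided; at these prevalences stratification changes little).

## The encoder and LoRA

The encoder is the standard post-norm transformer: token embedding plus
fixed sinusoidal positional encoding, then $L$ layers of multi-head
scaled-dot-product attention ($\mathrm{softmax}(QK^\top/\sqrt{d_k})V$),
residual + layer norm, position-wise FFN
($\max(0, XW_1 + b_1)W_2 + b_2$), residual + layer norm. Desk-scale defaults
are $H = 64$, 4 heads, $L = 2$, $d_\mathrm{ff} = 128$; the BERT-scale
configuration ($H = 768$, 12 heads, 12 layers) is constructible but required
by nothing — every property tested is scale-free.

Attention projections carry LoRA adapters: the effective weight is
$W_0 + BA$ with $W_0$ frozen, $A \in \mathbb{R}^{r \times k}$ Gaussian
(sd 0.02), $B \in \mathbb{R}^{d \times r}$ zero-initialized, default rank
$r = 8$, and **no** $\alpha/r$ scaling — the update is literally $BA$. Zero
$B$ makes a fresh adapter bitwise identical to the base model, and training
never writes to $W_0$ (checked by identity in the suite). All four
projections ($W_Q, W_K, W_V, W_O$) are adapted.

Numerical choices worth recording:

* Embeddings (init sd 0.02) are multiplied by $\sqrt{H}$ before the
  positional encoding is added, the original-transformer convention;
  without it the unit-scale PE swamps the embeddings and token identity
  never reaches the classifier. The same scaling amplifies embedding
  gradients by $\sqrt{H}$, which at desk scale acts as a useful
  per-parameter learning-rate boost for the embedding table. Both knobs
  are exposed (`emb_init_sd`, `pe_scale`) for users who want a different
  balance.
* Layer norm uses $\varepsilon = 10^{-5}$; softmax subtracts the row
  maximum.
* The tokenizer lowercases and splits on non-alphanumeric runs (English
  dialect) or characters (Chinese); ids are dense from 0 with reserved
  `pad`/`unk`/`cls`. Every encoded sequence is prefixed with `cls`, so no
  stream is ever empty (a structured report with zero present categories
  and MCI off would otherwise have no tokens).

## Fusion and the classifier

Let $F_\mathrm{free}$ and $F_\mathrm{struct}$ be the two streams' token
feature matrices. The five strategies:

| strategy | rule | fused width |
|---|---|---|
| concatenation (default) | stack token rows, then pool | $H$ |
| concatenation, feature axis | pool each stream, concatenate | $2H$ |
| addition | pool each, add | $H$ |
| average pooling | pool each, average | $H$ |
| max pooling | pool each, elementwise max | $H$ |
| cross-attention | attention(Q=free, K=V=struct), then pool | $H$ |

Pooling is the mean over the sequence axis (max available via `pool =
"max"`). The fused vector feeds a single fully connected layer and a
two-class softmax; class 1 is "Suggestion for Biopsy". The sequence-axis
reading of "concatenation then pooling" is the default; the feature-axis
variant sits behind `concat_axis = "feature"` because the pooled-vector
reading is equally defensible and lets the head weight streams separately.

**Training.** Cross-entropy, mini-batch gradient descent with classical
momentum 0.9 and global gradient-norm clipping at 1.0, fixed learning rate
(default 0.3), batch 32, 8 epochs. Momentum and clipping are deliberate
additions to plain fixed-rate descent: at this scale plain descent either
needs an epoch budget that buries the ablation contrasts in seed noise or
diverges outright once the rate is raised; momentum with clipping is the
minimal standard remedy and keeps every contract (a zero learning rate
still changes nothing, identical seeds still give identical histories).
The backward pass is analytic, implemented in C++ (RcppArmadillo) with
mini-batch sequences packed into single large matrix products; it is
verified against central finite differences for every fusion strategy and
against the pure-R encoder for the forward pass. Training is deterministic
given the seed: initialization and shuffling happen in R's RNG, and the C++
core contains no randomness. The reference two-stage schedule (rates
3×10⁻⁴ and 10⁻⁶ over 5 and 10 epochs) ships as `fit_presets()`, not as
defaults — at desk scale those rates are far too small to move a freshly
initialized model.

**Attention maps.** `attention_weight_map()` reports, per stream, the
attention mass each token receives in the final layer, averaged over
queries and heads and normalized to 1 — the quantity usually rendered as
token heat. A caveat found empirically and worth stating: in this tiny
model, trained attention mass on `"not mentioned"` tokens is
indistinguishable from uniform (ratios within ±0.3% of 1, sign unstable
across seeds). The label signal of missingness flows through embeddings and
pooling without requiring attention to concentrate on the sentinel, so the
package does not claim — and its tests do not assert — the darker-sentinel
visualization effect a fully trained BERT exhibits; the map's contracts
(normalization, single-token degeneracy) are what is tested.

## Evaluation

**BERTScore.** For reference $x$ and candidate $\hat x$ with L2-normalized
contextual embeddings, precision is the mean over candidate tokens of the
best cosine against the reference, recall the converse, F their harmonic
mean (0 when $P + R = 0$). Greedy matching, no alignment constraint, no IDF
weighting, no baseline rescaling. Scores therefore live in $[-1, 1]$ in
principle; untrained random encoders produce strongly anisotropic
embeddings, so unrelated sentences score high in absolute terms — only
comparisons against the exhaustive pairwise-max oracle, self-match, and the
P/R duality are meaningful at desk scale, and those are what the tests
check. Category-wise scoring (`bertscore_structured()`) skips categories
where both sides are the sentinel.

**Classification metrics.** Precision/recall/F1 at threshold 0.5, macro
averaging by default (per-class values are always reported alongside;
micro-averaging, which for binary single-label data equals accuracy, is
available); AUC is the Mann–Whitney rank statistic with mid-rank tie
correction, `NA` with a message when only one class is present.

**Ablation harness.** `run_ablation()` takes a data frame of cells
(streams × fusion × MCI × PH), regenerates the seeded corpus per seed,
trains, evaluates on the test split, and aggregates mean ± sd; failures are
recorded per cell and the run continues.

## The directional experiments

Three contrasts mirror the ablation logic of structured-report
classification studies, run at n = 2000 records × 5 seeds with the
desk-scale encoder (sizes chosen as the smallest at which the contrasts
are stable):

* **MCI (structured stream).** Informative missingness ⇒ completing missing
  categories with the sentinel is expected not to hurt mean test AUC. The
  suite asserts this direction as stated; it is the one contrast that does
  not robustly materialize here (see the caveat below).
* **PH (free-text stream).** With label-linked PH clauses, stripping PH
  removes real signal ⇒ keeping it should not hurt.
* **Fusion.** On a corpus where the streams are complementary, both-stream
  concatenation should match or beat each single stream. Complementarity is
  constructed by withholding `axillary_lymph_nodes` from the free text
  (label weight 1.2) while the structured stream never carries PH (weight
  1.0) — the two withheld signals are deliberately of comparable strength so
  neither stream dominates by construction.

Each contrast is reported as paired per-seed differences; the suite asserts
the mean direction and that a sign test does not contradict it at α = 0.05.
Margins are a few AUC points against seed noise of similar order — these
are directional claims about the generator's conditions, not effect-size
claims about clinical data.

A caveat on the MCI contrast, found empirically and worth being explicit
about: in a pooled from-scratch encoder the sentinel adds no *information*
beyond what token absence already encodes. Without MCI, the absence of a
category's name tokens is directly visible to the pooled representation;
with MCI, the sentinel must be *bound* to its category through position or
attention before it says which category is missing, and a two-layer H = 64
encoder trained from scratch does not reliably learn that binding. The
measured paired differences accordingly hover within a few hundredths of
zero with an unstable sign, and the sign test cannot distinguish the
contrast from zero in either direction. The MCI benefit reported for fully
pretrained encoders plausibly rests on exactly the representation machinery
a desk-scale model lacks; this package reports the contrast it measures
rather than claiming the effect.

## Known limitations

* The synthetic dialect is English, template-generated, and exactly
  parseable; nothing here measures robustness to real clinical narrative,
  Chinese text, negation, or reporting-style drift.
* The reference structurer is a lexicon matcher; the LLM-backend interface
  is a contract plus a mock, not a client.
* BERTScore uses untrained encoders at desk scale; absolute scores are not
  comparable to published values computed with pretrained embeddings.
* The attention-saliency visualization effect on sentinel tokens does not
  reproduce at this scale (see above).
* Binary labels only; BI-RADS sub-grades are not modelled.
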