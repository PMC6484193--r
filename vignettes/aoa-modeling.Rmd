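---
title: "Modeling age-of-acquisition effects in word naming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling age-of-acquisition effects in word naming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The phenomenon and the model

Words acquired early in life are named faster and more accurately than
words acquired late, even after frequency and spelling–sound consistency
are controlled — the age-of-acquisition (AoA) effect. Connectionist
accounts attribute it to the learning dynamics of layered networks
trained by error back-propagation: early items shape the weights while
the logistic units still operate near their maximum-slope region; as
training drives net inputs away from zero, the derivative term
$\sigma'(z) = \sigma(z)(1-\sigma(z))$ shrinks, later items receive
smaller effective updates, and the network has progressively less
plasticity to give them. The same entrenchment makes early items more
resistant to damage.

`aoanet` implements this account end to end for a reading (orthography →
phonology) network:

* a two-layer logistic feedforward network with 132 input units
  (33 letters × 4 positional slots), 100 hidden units, and 112 output
  units (28 phonemes × 4 slots), weights initialised uniformly in
  $[-0.5, +0.5]$;
* online error back-propagation on the delta rule
  $\delta_o = (o - t)\,o(1-o)$ (i.e. $E = \tfrac12\sum(o-t)^2$) with
  learning rate 0.01 or 0.05 and momentum 0.9 (0 in the no-momentum
  control), patterns shuffled every epoch;
* an alternative batch optimizer, Fahlman's Quickprop (secant step
  toward the vertex of a per-weight parabola, maximum growth factor
  $\mu = 1.75$, additive gradient term while the slope keeps its sign,
  sigmoid-prime offset $+0.1$ on the output derivative);
* staged curricula contrasting an early-acquired against a
  late-acquired word group, graded hidden-unit lesioning, and the
  item-level analysis of covariance used for behavioural data.

The per-item error *metric* reported everywhere is the summed squared
error $\sum_k (o_k - t_k)^2$ over the 112 output units (28.0 for an
untrained network whose outputs all sit at 0.5); whole-word correctness
additionally decodes each slot block (argmax if the maximum activation
reaches 0.5, blank otherwise) and compares it with the target.

## The synthetic lexicon

The behavioural materials this line of work uses — several hundred
monosyllables grouped by the school grade at which they first appear —
are not distributable, so the package generates artificial lexica with
the same manipulable statistics ([`generate_lexicon()`]):

* five grade groups of 82/62/56/49/78 words (327 total) by default;
* four positional slots per word: two onset letter slots (the second
  occupied with probability 0.5), an always-occupied vowel/body slot,
  and a coda slot (probability 0.7); blanks encode as all-zero blocks;
* a per-slot letter→phoneme rule table drawn once per lexicon; in
  `quasi_regular` mode each word's pronunciation follows the table
  except for a Bernoulli(`inconsistency_rate`) subset of *exception*
  words whose body/rime slots (3–4) receive a deviating phoneme — the
  mostly-regular-with-exceptions structure of a deep orthography. The
  default rate of 0.2 puts roughly one word in five off-rule, a level at
  which consistency measurably matters without making the mapping
  unlearnable;
* integer frequencies $1 + \mathrm{Geom}(0.5)$ (most words 1–3),
  identically distributed in every grade so frequency and grade are
  unconfounded unless configured otherwise;
* a slot-level Coltheart-N consistency measure: the number of other
  words whose spelling differs in exactly one slot, counted within the
  lexicon.

`arbitrary` mode draws pronunciations independently of spellings,
emulating the unstructured random pattern sets of earlier modelling
work; a test verifies near-zero plug-in mutual information between
spelling and pronunciation slots in this mode.

What the generator does *not* emulate: real Farsi orthography or
phonology, grade-dependent word length or difficulty, semantic
variables, and any property of the human error distribution. Passing
simulations therefore show that the *mechanism* reproduces the
qualitative phenomena on materials with the right statistical skeleton,
not that the model fits the original behavioural data.

## The seven simulation protocols

All canonical protocols contrast the grade-1 group ("early", 82 words)
with the grade-2 group ("late", 62 words):

| id | stages | hyperparameters |
|----|--------|-----------------|
| sim1 | early ×1, 150 epochs → early ×1 + late ×2, 150 epochs | lr 0.01, momentum 0.9 |
| sim2 | as sim1, interleaved stage 300 epochs | lr 0.01, momentum 0.9 |
| sim3 | order reversed (late first, early the newcomer ×2) | lr 0.01, momentum 0.9 |
| sim4 | 300 + 300 epochs | lr 0.05, momentum 0.9 |
| sim5 | 1500 + 1500 epochs | lr 0.05, momentum 0 |
| sim6 | sim1, then lesioning of the trained network | — |
| sim7 | sim1 stages, batch Quickprop | lr 0.01, μ 1.75 |

The newcomer group's multiplicity of 2 presentations per epoch encodes
frequency equalisation: over sim1's two stages every item totals 300
presentations (150 + 150 for the first-trained group, 150 × 2 for the
newcomer). "Doubled interleaved training" in sim2 is read as running the
interleaved stage for twice the epochs; the alternative reading (two
repetitions of both stages) can be produced with the `epochs` override.
For sim4 the textual reading (doubled epochs, 300 + 300, lr 0.05) is
implemented rather than the 3000-epoch figure caption.

Evaluation is a clean forward pass over the union of stage items at
epoch 0, every `eval_every` epochs (default 10), and at the final epoch.
The headline statistic is the **AoA gap**: mean late-item SSE minus mean
early-item SSE at the end of training; positive values mean the early
group is read better.

## Simulation scale, and why the epochs are not shortened

The qualitative effects are properties of a *loaded* network. With the
full materials (144 trained words on 100 hidden units) the mapping is
still being consolidated when training ends, and the entrenchment
advantage of the first-trained group survives the newcomers' frequency
advantage. On small desk lexica (tens of words) the same network
reaches floor on both groups well before the protocol ends, after which
the ×2 multiplicity slowly *reverses* the gap — the effect is transient
rather than absent. The packaged tests and the acceptance script
therefore run the protocols at the full materials scale with the
protocols' own epoch counts, across 5–10 independent seeds (each seed
draws its own lexicon, initial weights and presentation orders), and
treat each simulation as a directional sign test across seeds. The
compiled training loop makes this cheap (roughly 25–60 µs per pattern
presentation; a complete sim1 run takes a few seconds).

Two statistics deserve a note:

* **Order reversal (sim3).** The raw sign of sim3's gap confounds
  training order with a materials asymmetry: the first-trained set in
  sim3 is the *smaller* (62-word) group, so entrenchment is weaker and
  a couple of seeds end in near-zero ties. The sharper statistic is the
  within-seed contrast gap(sim1) − gap(sim3) > 0 — the advantage moves
  with training order when group identity, materials and seeds are held
  fixed — and that is what the acceptance test asserts (the raw sign is
  additionally required for a majority of seeds).
* **Quickprop on arbitrary patterns.** With flat-spot elimination,
  Quickprop fully masters 144 arbitrary slot-coded patterns within the
  sim1 epoch budget, so no gap remains in either direction. Earlier
  random-pattern work that found a surviving AoA effect under Quickprop
  used a far higher pattern-to-capacity load and an incremental
  vocabulary regime; with this paper's materials sizes the package does
  not reproduce that contrast, and its acceptance check is expected to
  fail. The finding the package does reproduce is the structured-lexicon
  one: Quickprop flattens the AoA effect that back-propagation shows.

## Why Quickprop needs its canonical details

The simplified "secant step with a gradient fallback" version of
Quickprop converges so slowly on this task that the late group never
approaches the early group, *reversing* the intended contrast. Two
standard components of Fahlman's algorithm matter here: the additive
gradient term (taken while the error slope keeps its sign) keeps weights
moving between secant jumps, and the sigmoid-prime offset
($\sigma' + 0.1$ on output units) lets saturated units keep learning —
which is precisely the "flexibility" that eliminates the AoA effect.
Both are implemented; `quickprop_step()` documents the exact rule. The
1-D quadratic property still holds: after a bootstrap step that crosses
the minimum, the next step is the pure secant jump and lands exactly on
the vertex.

## Lesioning

`lesion_network()` damages `round(severity × 100)` hidden units
(round half up), selected uniformly per replicate: `zero_weights`
silences a unit's incoming and outgoing weights and bias;
`add_noise` adds zero-mean Gaussian noise (sd 0.5 by default, the
half-width of the initial weight range) to the same parameters, so the
unit's net input is disturbed rather than removed. The experiment grid
(severities 0.05/0.10/0.20, both methods, 20 replicates) reproduces
graded degradation: mean error rises monotonically with severity for
both groups, and the early group's advantage survives damage (the
absolute late−early gap is approximately preserved across severities
rather than widening — a weaker form of differential vulnerability).

## The covariance analysis

`ancova()` mirrors the behavioural item analysis: OLS of the per-item
error on frequency, consistency, and the 5-level grade factor, with
sequential (Type-I) sums of squares in that order, so the covariates
absorb their variance before the acquisition factor is tested (with 327
items this yields 4 df for the grade factor and 320 error df). A
polynomial linear-trend contrast over the covariate-adjusted grade means
is reported alongside. Sequential SS is a deliberate choice matching the
covariate-control narrative of such analyses; with the no-covariate
two-group design the grade F reduces exactly to the squared pooled t.

## Numerical and reproducibility choices

* Readout threshold 0.5 with lowest-index tie-break (matches 0/1
  logistic targets); unit ordering is slot-major and documented, so
  saved networks are portable.
* One master seed per run spawns independent streams (lexicon,
  initialisation, shuffling, lesion replicates) through a fixed integer
  recurrence; identical configurations reproduce outputs byte for byte.
* The compiled loop and the R-level `backprop_update()` implement the
  same arithmetic; a test drives both over the same shuffle stream and
  asserts agreement. Training aborts with a diagnostic if weights
  become non-finite; a zero-gradient update leaves the state exactly
  unchanged.
* Back-propagation uses no weight decay and no target clipping.
  Quickprop folds a small decay term into its slope
  (`quickprop_decay`, default 1e-4, a standard component of published
  implementations): without it the maximum-growth rule can escalate
  steps without bound on plateaus and occasionally overflows. Quickprop
  memories and the momentum memory live in the saved network state, so
  training can resume losslessly from a JSON snapshot.

## Known limitations

* Artificial materials: conclusions transfer to the mechanism, not to
  Farsi (or any) orthography in detail.
* The human three-level error scale and reaction times are not modelled;
  the ANCOVA operates on whatever error column it is given.
* The differential-vulnerability effect under lesioning is a
  preservation, not an amplification, of the early advantage in this
  implementation.
* Quickprop on unstructured pattern sets converges to ceiling at this
  capacity; contrasts that depend on partial mastery are out of reach
  with the given materials sizes.
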