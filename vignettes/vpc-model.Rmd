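---
title: "The visual place cell generation model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The visual place cell generation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vpcsim)
```

## The model

Place cells are hippocampal neurons that fire at a high rate only when the
animal occupies a restricted region of space. `vpcsim` simulates a purely
vision-driven route to such cells: *visual place cells* (VPCs) whose firing
is determined entirely by the landmarks currently perceived, with no
self-motion (path-integration) input. The model has four stages, executed
once per location-update step of an exploring agent.

**1. Landmark perception.** The world is a rectangular arena containing
point landmarks, each carrying a recognition label (its identity), a
position, and a saliency value. The agent perceives every landmark whose
Euclidean distance lies in the closed recognition annulus
$[d_{\min}, d_{\max}]$, obtaining for each a four-tuple: identity,
saliency, bearing and distance. Bearings are measured clockwise from
north, an *absolute* reference: if bearings were measured against the
running direction, the same physical location would produce different
percepts at different times, destroying the location specificity the model
is meant to produce.

**2. Place code.** The set of perceived landmark tuples at one step is the
*place code* — the model's entire representation of "where am I". An
empty place code (no landmark in range) is valid and carries no location
information.

**3. Similarity measure.** Every recruited cell stores the place code it
memorized at recruitment. Its firing rate at the current percept is a
saliency-weighted sum of Gaussian similarities over the *matched*
landmarks (identities present in both codes):

$$
f_k \;=\; \sum_{i \in \mathrm{matched}} w_i \,
\exp\!\left(-\,\frac{w_d\,(d_i - d_i^k)^2}{\sigma_d^2}
            -\,\frac{w_\theta\,(\Delta\theta_i)^2}{\sigma_\theta^2}\right),
\qquad w_i = \frac{s_i}{\sum_{j=1}^{N(t)} s_j},
$$

where $d_i, \theta_i$ are the current distance and bearing of landmark
$i$, $d_i^k, \theta_i^k$ the values memorized by cell $k$, and $s_i$ the
saliencies of the current code. $\Delta\theta_i$ is the bearing difference
wrapped into $[-180^\circ, 180^\circ]$ before squaring. $f_k$ lies in
$[0, 1]$, and equals 1 exactly when the current percept reproduces the
stored one.

**4. Recruitment.** The rates of all recruited cells are compared and the
winner (maximal rate, ties broken toward the earliest-recruited cell) is
compared with the firing-rate threshold (FRT). If the winner is *strictly
below* the FRT — or no cell exists yet — the current place code is
memorized and a new cell is recruited. Recruitment therefore closes every
coverage gap: immediately after any step with a nonempty percept, the
winning rate at that percept is at least the FRT. This invariant is what
makes the population's overlapped firing fields tile the whole explored
space, and it is asserted as a test across a full baseline run.

## Parameters

| parameter | units | default | role |
|---|---|---|---|
| `width`, `height` | m | 40, 40 | arena dimensions |
| `n_landmarks` | – | 100 | landmarks, uniform over the arena |
| `saliency_mode` | – | `equal` | all saliencies 1 (or i.i.d. uniform) |
| `d_min`, `d_max` | m | 10, 15 | recognition annulus (closed) |
| `v_max` | m/s | 5 | maximal agent speed |
| `dt` | s | 1 | location-update period |
| `n_steps` | – | 4000 | steps per exploration run |
| `sigma_d2` | m² | 25 | distance AFFF ($\sigma_d = 5$ m) |
| `sigma_theta2` | deg² | 100 | orientation AFFF ($\sigma_\theta = 10^\circ$) |
| `w_d`, `w_theta` | {0,1} | 1, 1 | enable distance / orientation terms |
| `frt` | – | 0.2 | firing-rate threshold |
| `resolution` | m | 0.5 | rate-map bin side |

The two AFFF values (adjustment factors of the firing field) control how
fast similarity decays with mismatch, hence the spatial extent of each
firing field: enlarging them produces fewer, broader fields; shrinking
them raises representation precision at a higher memory cost. The FRT
moves the recruitment margin: a higher threshold demands a closer match
before an existing cell "covers" a location, so more cells are recruited
and individual fields are effectively narrower.

$\sigma_\theta^2$ is interpreted in squared *degrees*: $\sigma_\theta =
10^\circ$ is a plausible angular tuning width, and the package's analytic
test values (e.g. $e^{-4}$ for a wrapped $20^\circ$ bearing error) pin
this convention. An interpretation in squared radians would make the
orientation term essentially inert; simulations with the orientation term
disabled recruit so few, so broad cells that the population cannot
represent the arena at the baseline threshold, which rules that reading
out.

## What the simulation emulates — and what it does not

The synthetic world stands in for a vision pipeline: real systems extract
landmarks from camera images and score their saliency; here landmarks are
abstract identified points, recognition is perfect within the annulus,
and measurements are noise-free. Consequently the simulator probes the
*coding* properties of the similarity-and-recruitment scheme, not its
robustness: passing tests say nothing about misrecognition, occlusion,
bearing/range noise, non-uniform landmark density, or saliency estimation
errors in real scenes. The perception stage is deliberately an interface
(any provider of place codes can replace the annulus rule) so such
extensions do not touch the model core.

The agent's free-space heading behaviour is a design choice. The default
`wander` policy perturbs the heading by a turn drawn uniformly on
$[-30^\circ, +30^\circ]$ each period, giving dense, diffusive coverage;
`uniform` redraws the heading every period, and `fixed` changes heading
only through specular wall reflections (a billiard). Because bearings use
the absolute north reference, firing depends on *position* only, and all
three policies produce statistically indistinguishable recruitment counts
at the baseline conditions — the choice is about trajectory appearance,
not about the coding results. Speed is redrawn uniformly on
$(0, v_{\max}]$ each period; wall hits reflect specularly (normal
component negated), handled axis-wise so corner hits resolve
deterministically.

## Numerical choices

- **Annulus endpoints are included** (closed interval): a landmark at
  exactly $d_{\min}$ or $d_{\max}$ is perceived.
- **Angle wrapping**: bearing differences are reduced modulo 360 into
  $[-180^\circ, 180^\circ)$ before squaring; without this, a $1^\circ$
  physical difference across north would register as $359^\circ$.
- **Weight normalization**: $w_i$ is normalized over *all* $N(t)$
  landmarks of the current code. Landmarks that appear only in the
  current code therefore dilute the weights of matched ones, penalizing
  scene change beyond pure geometric mismatch. The alternative —
  normalizing over matched landmarks only, which forgives scene turnover —
  is available via `weight_mode = "matched"` for sensitivity analysis;
  it recruits markedly fewer cells because fields stop shrinking with
  annulus turnover.
- **Strict threshold**: "below FRT" is a strict `<`; a winner exactly at
  the threshold does not recruit. Winner ties break toward the lowest
  cell id, making runs bit-reproducible.
- **Empty percepts never recruit**: the weight normalization is undefined
  at $N(t) = 0$ and an empty code memorizes nothing useful.
- **Rate maps**: per-cell maps store the *mean* rate over the trajectory
  points in each bin; the population map takes the bin-wise *maximum*
  across cells (the strongest responder). Unvisited bins are `NA`, never
  0 — conflating "not visited" with "not firing" would corrupt field-area
  metrics. The default 0.5 m bin resolves $\sigma_d = 5$ m fields while
  keeping per-bin visit counts dense over 4000 steps.
- **Determinism**: landmark layout and trajectory have separate seeds
  derived from the master seed, so a sweep can hold the layout fixed
  across parameter values within a replicate while varying it across
  replicates. Rerunning a bundle's snapshot config reproduces the cell
  registry byte-for-byte.

## Parameter studies

`sweep()` runs one parameter across values with replicated runs and
`trend_check()` compares replicate-mean cell counts in a stated
direction. The suite asserts four trends at the baseline conditions, each
with 5 replicates:

- FRT over $\{0.1, 0.2, 0.3, 0.4\}$: counts strictly increase;
- recognition annulus over 5–10, 5–15, 5–20 m: counts strictly decrease
  (longer recognition distance → more landmarks per percept and slower
  percept turnover → broader fields → fewer cells);
- AFFF quadrupled (both $\sigma^2$ scaled ×4): counts decrease;
- steps over $\{500, 1000, 2000, 4000, 8000\}$: counts increase with
  shrinking successive differences, saturating as exploration approaches
  full coverage.

Exact per-condition counts are not asserted — they depend on the random
layout and trajectory — only the orderings of replicate means.

## Problem sizes used by the tests

Unit tests run at reduced sizes (runs of 150–600 steps) chosen so each
property is exercised well away from degenerate regimes; the end-to-end
checks use the full baseline run (4000 steps, 10 seeds for the mean
count, $10^5$ steps for motion invariants) and the four sweeps above.
The brute-force similarity oracle — scalar loops, linear search,
iterative angle wrapping, written independently of the vectorized
implementation — is compared on 1000 random small place-code pairs to
$10^{-12}$.

## Known limitations

- No noise model anywhere (perception, motion, recognition); the
  extensions would attach at the `perceive()` interface.
- No forgetting or pruning: the population only grows, and revisiting a
  changed scene recruits rather than updates.
- The recruited count at the baseline conditions is a packing-like
  quantity: it measures how many stored percepts are needed before every
  visited location finds a winner above threshold. It is sensitive to the
  similarity measure's exact decay scales, and with the defaults the
  model settles around a hundred-odd cells per run (the acceptance script
  computes the exact mean); reading of the decay convention materially
  changes this number, as the `weight_mode` comparison shows.
- Non-rectangular arenas, obstacles and occlusion are out of scope.
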