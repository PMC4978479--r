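---
title: "Simulating chromosome territories as confined bead chains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating chromosome territories as confined bead chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctsim)
```

## The model

During interphase, each decondensed chromosome occupies a distinct region
of the nucleus — a chromosome territory (CT). `ctsim` asks what CT
arrangements look like when chromosome placement is governed by *nothing
but* geometry and chance: chromosomes are grown as chains of spherical
1 Mbp chromatin domains ("beads", radius $r_b$, default 250 nm) inside a
spherical nucleus, subject only to excluded-volume constraints. Comparing
arrangement frequencies from this fully probabilistic null model against
microscopy data indicates whether real nuclei order their chromosomes
non-randomly.

One simulated nucleus is built in six steps:

1. **Parameters.** A `species_config` fixes the karyotype: the number of
   chromosome pairs, per-arm chain lengths in the condensed state
   (`l_arm_c`, beads) and after decondensation (`l_arm_d`, 1 Mbp domains),
   geometry bounds and tolerances. The centromere is bead index 0 of each
   chromosome and belongs to neither arm, so a chromosome of $M$ Mbp has
   arm lengths summing to $M - 1$.
2. **Nucleus.** A sphere at the origin with radius $R$ drawn uniformly
   from $[R_{\min}, R_{\max}]$.
3. **Nucleolus.** A second sphere whose volume is a uniform fraction
   $v \in [vol_{\min}, vol_{\max}]$ of the nuclear volume, i.e. radius
   $r = (v R^3)^{1/3}$; its centre is redrawn until the nucleolus lies
   strictly inside the nucleus. It is pure excluded volume: no chromatin
   may intrude.
4. **Centromeres.** One seed bead per chromosome, placed by rejection
   sampling. A candidate position $p$ is accepted iff
   $|p| < R - (r_b + 5\varepsilon_2)$ (containment, C1),
   $|p - no| > r + r_b + \varepsilon_2$ (nucleolus clearance, C2) and
   every previously placed centromere is farther than
   $2 r_b + \varepsilon_2$ (C3). All comparisons are strict.
5. **Condensed growth.** Each chromosome extends bead-by-bead from its
   centromere, bidirectionally along both arms, until the condensed arm
   lengths are reached. Each new bead sits at step distance from the arm's
   terminal bead, in a direction drawn from two independent uniform
   angles, and must pass the domain conditions: inside the nucleus
   ($|p| < R - r_b$, C1'), clear of the nucleolus (C2'), at least
   $2 r_b - 2\varepsilon_1$ from every bead of its own chromosome except
   its precursory bead (C3'), within the $d_1$ window of its own
   chromosome (C4) and at least $2 r_b + \varepsilon_2$ from every bead of
   every other chromosome (C5).
6. **Decondensation.** New domains are added along the whole chromosome,
   not only at chain ends: for each new bead a *precursory domain* is
   drawn uniformly from the existing beads of the arm being extended, the
   candidate is placed one step from it and screened by the same
   conditions, until every arm holds its decondensed domain count.

Whenever `restart_after` consecutive candidates are rejected, the whole
partly built model is discarded — nothing is kept — and construction
restarts from step 2 with fresh randomness. A batch run reports the
success rate as completed models over attempted runs.

## Numerical and design choices

**Angle convention.** The growth step uses the literal transformation
$dx = s\cos\theta\sin\phi$, $dy = s\sin\theta\sin\phi$, $dz = s\cos\phi$
with $\theta \sim U(0,\pi)$, $\phi \sim U(0,2\pi)$. This is not the
area-uniform sphere distribution (the polar angle is carried by $\phi$),
but it is rotationally symmetric about the z axis and every step has
exactly length $s$; chain growth only needs an unbiased, norm-preserving
step, and we keep the original convention for comparability.

**Step length.** Two subsequently drawn beads are tangent: the default
step is $2 r_b$, so a bead touches its precursory bead. A
`step_mode = "radius"` option shortens the step to $r_b$ (the literal
offset used in the original coordinate-generation formula); the C3'
exemption of the precursory bead then tolerates the resulting overlap
within a chain.

**Foreign-bead threshold.** The collision rule for beads of different
chromosomes uses $2 r_b + \varepsilon_2$: foreign chromatin must be
*farther* than own chromatin ($2 r_b - 2\varepsilon_1$), which is what
the condition "far enough from a foreign chromosome" and the $d_2$
distance window describe. The algebraically literal alternative
$2 r_b - 2\varepsilon_2$ — which would invert that relation — is kept
behind `paper_literal = TRUE` for comparison runs.

**Tolerances.** $\varepsilon_1$ and $\varepsilon_2$ are not published
numbers ("set up experimentally"); the defaults are
$\varepsilon_1 = 0.1\, r_b = 25$ nm and
$\varepsilon_2 = 0.2\, r_b = 50$ nm, both user-settable. They act as a
small intra-chromosome overlap tolerance and an inter-chromosome /
boundary clearance, respectively, and must satisfy
$\varepsilon_2 > \varepsilon_1 > 0$.

**Precursory redraw.** The precursory domain is re-drawn on every
rejected candidate, not fixed per placement. A bead in the crowded
interior of a territory often admits *no* legal neighbour position; if
the precursory draw were fixed, a single such bead would deterministically
exhaust the whole `restart_after` budget and no realistic model would
ever complete. Re-drawing makes the placement distribution a mixture over
feasible precursors, which is how "discard the coordinates and draw a new
set" is implemented here.

**Scheduling.** Chromosomes advance round-robin, one bead per chromosome
per round (condensed phase: alternating arms; decondensation: the arm
with the larger remaining deficit, ties to the top arm). The original
does not specify an order; a fair deterministic interleaving keeps runs
reproducible and avoids giving early chromosomes a packing advantage.

**Restart accounting.** One failure counter is shared by the entire
attempt (centromere seeding and both growth phases) and resets on every
successful placement, so a restart fires after exactly `restart_after`
*consecutive* failures. The default budget is 500&nbsp;000.

**Determinism.** All randomness flows through R's seeded RNG, including
the compiled rejection-sampling kernels (which call R's generator rather
than their own), so a fixed `(config, seed)` reproduces a byte-identical
model file.

## Defaults that stand in for unpublished measurements

The nuclear geometry of the original *B. distachyon* experiments is not
published. The preset uses nuclei of radius 3.5–4.0 µm (7–8 µm diameter,
typical of plant root meristem interphase nuclei) and a nucleolus
occupying 2–5% of the nuclear volume. Under the 540-domain diploid
karyotype this puts the chromatin at 13–20% of nuclear volume — packed
enough that collisions shape the territories, loose enough that
essentially every attempt completes. The per-chromosome condensed chain
lengths for Bd2–Bd4 are likewise not printed (only the 3.5–7.0 µm range);
they are interpolated linearly in Mbp content, giving chains of 14, 12,
12, 10 and 7 beads. Arm splits assume a 50:50 division for the
metacentric Bd1–Bd3 and 25:75 for the acrocentric Bd4–Bd5. All of these
live in the editable preset file
(`system.file("extdata", "set1_brachypodium.yaml", package = "ctsim")`).

These choices matter quantitatively: how often territories touch depends
directly on the chromatin volume fraction, so arrangement *frequencies*
shift with nucleus size even though the *class inventory* and all
geometric invariants do not.

## Downstream analysis

Two territories (or arms) are *associated* when the minimum
border-to-border distance between their bead sets — centre distance minus
$2 r_b$, floored at zero — is strictly below 500 nm. For a homologous
pair, the four arm pairings (top:top, bottom:bottom and the two cross
pairings) yield one of exactly five arrangement classes:

* `complete_separation` — no pairing associated;
* `top_top`, `bottom_bottom` — only that same-arm pairing;
* `both_arms` — both same-arm pairings;
* `top_bottom` — cross pairings only.

In composite cases same-arm evidence takes precedence over cross-arm
evidence (`both_arms` > `top_top`/`bottom_bottom` > `top_bottom`);
`details = TRUE` exposes the raw pairing booleans for auditing.
Heterologous pairs get a whole-territory `associated`/`separated` verdict
under the same threshold. Frequencies over replicate models are
tabulated per pair, and frequency tables can be compared with Pearson's
chi-squared goodness-of-fit test (`chisq_gof()`), e.g. simulated
arrangement counts against experimentally observed proportions.

The `top_bottom` class is the model's signature: it occurs in the
probabilistic simulation but has not been observed experimentally, which
is exactly the kind of discrepancy the null model exists to expose.

## A small worked run

```{r example, eval = FALSE}
cfg <- brachypodium_preset()
model <- simulate_nucleus(cfg, seed = 1)
model
classify_homologue_pair(model, 5)

batch <- simulate_batch(cfg, 50, seed = 1)
tabulate_arrangements(batch)
```

The test suite exercises replicate batches of 115 nuclei (the replication
level of the original analysis, a few seconds of computation); the
vignette keeps illustrative sizes small.

## What the synthetic models do and do not show

The generator emulates confined, excluded-volume chain growth with a
nucleolus and species-specific chain lengths. It does not model chromatin
fibre persistence length, loop extrusion, nuclear lamina attachment,
nucleolus-organising regions, or non-spherical nuclei — all territory
structure beyond crowding is out of scope by design. Passing tests
therefore certify the geometry, bookkeeping and statistics of the null
model, not biological fidelity of any particular arrangement frequency.
Known limitations: only one bead per domain is supported (`multi = 1`);
the C4 "close enough to own chromosome" window is nearly vacuous for
realistic nucleus sizes (its upper bound is close to $R$) and is checked
as stated; and wall-clock benchmarking of the original implementation is
not reproduced.
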