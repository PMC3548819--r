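---
title: "A semi-analytical model of transcription-factor target search in living bacteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A semi-analytical model of transcription-factor target search in living bacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

A lac repressor in an E. coli cell finds its operator in a few minutes, even
though the operator is a few dozen basepairs out of 4.6 million. The classical
explanation — facilitated diffusion, the alternation of 3D cytoplasmic
diffusion with 1D sliding along DNA — was established in dilute in vitro
conditions. Whether it still operates, and still helps, inside a crowded cell
where the chromosome is compacted into a sub-cellular nucleoid is a
quantitative question: the search time depends on the DNA conformation, the
non-specific binding and unbinding rates, and the two diffusion constants.

`fdsearch` implements a tractable in vivo model in three layers:

1. **Genome model.** The chromosome is coarse-grained into $n$ equal
   "blobs" (spheres of gyration radius $R_g$ holding $N_{bp}$ basepairs
   arranged as one loop) forming a *closed self-avoiding walk* on a cubic
   lattice of constant $a = 2R_g$ that fills the nucleoid volume. The
   nucleoid lattice is centred in a larger lattice representing the whole
   cell.
2. **Walk statistics.** The searcher moves as a nearest-neighbour random
   walk on the cell lattice. Four numbers summarise the geometry: the mean
   number of steps $\bar n_f$ and of non-target blob encounters $\bar m_f$
   until the first arrival at the target blob from a uniform start, and the
   analogous $\bar n_r, \bar m_r$ for walks returning from a site adjacent
   to the target.
3. **Blob-level kinetics.** What happens inside a blob — binding, sliding,
   escaping — is solved in closed form, and the pieces are assembled into
   the mean total search time.

## Microscopic kinetics

**Binding within a blob.** After entering a blob the searcher diffuses
($D_3$) through a locally random DNA coil and binds non-specifically at rate
$k_a\rho$, where $\rho = N_{bp}/(\tfrac43\pi R_g^3)$ is the coil's DNA
density (homogeneous-coil convention; exposed in the configuration). The
blob's domain of influence ends at a concentric absorbing shell of radius
$Z R_g$. For a uniform start inside the coil, the splitting probability of
binding before escape is

$$P_b \;=\; 1-\frac{3\,\xi(x)}{x^{2}\,\bigl(1+(1-1/Z)\,\xi(x)\bigr)},
\qquad \xi(x) = x\coth x - 1,\qquad
x = R_g\sqrt{k_a\rho/D_3}.$$

$P_b$ rises monotonically with $k_a$ and falls with $D_3$; the model is
meaningful only for $D_3>0$ and $Z>1$. The conditional mean times to bind
(given binding) and to escape (given no binding) solve the corresponding
conditional mean-first-passage boundary-value problems; the package
evaluates the exact piecewise radial solutions (an interior
$\{1/k,\ \cosh\kappa r,\ \sinh(\kappa r)/r\}$ family matched to an exterior
$\{r^2, r, 1, 1/r\}$ family) with all hyperbolic factors arranged as bounded
ratios, so the evaluation is stable from $x\approx0.02$ up to arbitrarily
large $x$. Below $x=0.02$ the conditional times are flat in $x$ (corrections
are $O(x^2)$, relative error under $4\times10^{-4}$) and the plateau value is
used; $k_a=0$ uses the classical uniform-start exit time
$R_g^2(Z^2-3/5)/(6D_3)$ exactly.

**Sliding.** A bound searcher starts uniformly on the blob's DNA stretch
and diffuses along it ($D_1$) while dissociating at rate
$k_{off}$. Because the target sits in the middle of the blob's DNA, the 1D
problem uses the one-sided stretch $L = N_{bp} l_{bp}/2$ with the target
absorbing at one end and a reflecting boundary (compaction obstructions) at
the other. With the sliding length $\lambda=\sqrt{D_1/k_{off}}$ and
$w = L/\lambda$:

$$P_t = \frac{\tanh w}{w},\qquad
t_{succ} = \frac{1}{2k_{off}}\Bigl(1-\frac{2w}{\sinh 2w}\Bigr),\qquad
t_{fail} = \frac{1}{k_{off}} - \frac{P_t\,t_{succ}}{1-P_t}.$$

$t_{fail}$ follows from the law of total expectation together with the
unconditional mean bound time $(1-P_t)/k_{off}$. Note that $t_{succ}$ tends
to the finite value $1/(2k_{off})$ as sliding vanishes — harmless, because
$P_t\to0$ in the same limit. Target detection happens **only** via sliding:
with $k_a=0$ the search never succeeds. Dissociation and re-association
positions are taken as uncorrelated, so every binding episode within a visit
uses the same $P_t$.

**Blob visits as a small Markov chain.** Entering unbound (U), the searcher
binds with probability $P_b$ (B) or leaves; from B it detects the target
with probability $P_t$ (target blob only) or returns to U. The expected
number of B↔U loops per visit is $P_b/(1-P_b(1-P_t))$, reducing to
$P_b/(1-P_b)$ in blobs without target, and the per-visit detection
probability is $p = P_bP_t/(1-P_b(1-P_t))$. Conditional visit durations
(successful / failed) are computed exactly from the two-transient-state
absorbing chain; a failed non-target loop keeps the memoryless bound
lifetime $1/k_{off}$.

## The mean search time

One lattice step takes $\tau = a^2/(6D_3)$ (the standard simple-cubic
correspondence reproducing MSD $=6D_3t$), and each encounter with a
non-target blob costs the mean visit dwell
$\tau_{nt} = \frac{P_b}{1-P_b}(t_{bind}+1/k_{off})+t_{esc}$. The total is
assembled as

$$\bar t \;=\; \underbrace{\bar n_f\,\tau + \bar m_f\,\tau_{nt}}_{t_{first}}
\;+\; \underbrace{\frac{1-p}{p}\Bigl(t^{visit}_{fail} + \tau + \bar
n_r\,\tau + \bar m_r\,\tau_{nt}\Bigr)}_{t_{returns}}
\;+\; \underbrace{t^{visit}_{succ}}_{t_{success}},$$

an exact three-term decomposition. The single $\tau$ inside the return term
is the exit step from the target site onto the neighbouring site where each
return walk starts; this reading (dwell charged before the return walk, plus
one exit step) was fixed by requiring agreement with an event-level
simulation of the whole scheme (`full_search_oracle()`), which reproduces
the formula within Monte Carlo error on small conformations. Because the
formula is linear in the walk counts and the per-visit outcomes are
independent of the walk, plain means are exact inputs here — no
distribution-level information is needed at the mean level.

The **bound-time fraction** keeps only the bound parts of every term
($1/k_{off}$ lifetimes and the sliding episodes) over $\bar t$.
`calibrate_association_rate()` inverts it for $k_a$ — it is monotone in
$k_a$, so a `uniroot` search on $\log_{10}k_a$ (relative tolerance
$10^{-6}$) is reliable — matching the measured 87% non-specifically bound
fraction of lac repressor. **Local (colocalised) searches** drop
$t_{first}$.

## Default parameters

| parameter | set a | set b | unit | why |
|---|---|---|---|---|
| $R_g$ | 20 | 40 | nm | structural-unit sizes seen by AFM / FCS |
| $N_{bp}$ | 10 | 50 | kbp/blob | measured domain sizes; genome 4639 kbp gives 464 / 92 blobs |
| nucleoid | 1.39 × 0.48 | — | µm | cylinder, as lattice 35×11×11 (a), 17×5×5 (b) |
| cell | 2.5 × 0.8 | — | µm | cylinder, as lattice 63×18×18 (a), 31×9×9 (b) |
| $D_3$ | 3×10⁶ | — | nm²/s | in vivo cytoplasmic diffusion of lac repressor |
| $D_1$ | 4.6×10⁴ | — | nm²/s | in vivo sliding diffusion |
| $l_{bp}$ | 0.34 | — | nm | basepair rise |
| $k_{off}$ window | 200–3333 | — | 1/s | measured residence times 0.3–5 ms |
| $Z$ | $\sqrt{23/5}\approx2.145$ | — | — | see below |
| ensembles | 3 | 5 | conformations | defaults; scatter between conformations is ~2% |

Cylinders become cuboids by conserving the cross-section area
(edge $=d\sqrt{\pi}/2$) and rounding edge lengths to the nearest number of
lattice constants (half away from zero); the exact lattice sizes can be
forced through `lattice_geometry()` directly.

**Choice of the shell ratio $Z$.** $Z$ fixes where a blob's influence ends
and is the one genuinely free microscopic parameter. We set
$Z=\sqrt{23/5}$, the unique value at which the no-binding escape time
$R_g^2(Z^2-3/5)/(6D_3)$ equals the lattice step time $a^2/(6D_3)$
($a=2R_g$). Then, in the limit of vanishing association rate, traversing a
blob site costs exactly one step time and the search time collapses to the
homogeneous-lattice first-passage result — the correct small-$x$ asymptotic
for an inert searcher. All closed forms are implemented for general $Z>1$,
so this is a default, not an assumption.

**Units of $k_a$.** $k_a$ is the intrinsic per-basepair non-specific
association rate in nm³/s; only the combination $x=R_g\sqrt{k_a\rho/D_3}$
enters the formulas. In practice $k_a$ is not chosen but calibrated.

## What the generator emulates — and what it does not

`generate_genome()` grows a minimal loop spanning the nucleoid's long axis,
inserts random "hooks" (+2 blobs each, confined and self-avoiding) until the
blob count is reached, and equilibrates with 10⁵ counted moves of the
Madras–Orlitsky–Shepp polygon move set (sub-chain inversions, reflections,
rotations; symmetric proposals, so accepted states sample confined polygons
uniformly — verified by exhaustive enumeration on small boxes). Counting
follows a two-stage rule: proposals breaking self-avoidance are rejected
without being counted, self-avoiding but unconfined proposals are rejected
*and* counted; `count_all = TRUE` switches to counting everything (the two
readings differ only in how fast the attempt budget is consumed).

This emulates: a compacted, confined, uniformly-sized-domain chromosome with
an even number of blobs and the target in the middle of the chain. It does
**not** emulate supercoiling, nucleoid-associated proteins, heterogeneous
domain sizes, DNA motion during the search (conformations are frozen after
centring), intersegmental transfer, or anomalous cytoplasmic diffusion.
Passing tests therefore validate the model's internal consistency and its
published phenomenology, not those excluded mechanisms.

## Numerical and convention choices

* **Blob count** rounds $\mathrm{genome/blob}$ to the nearest even integer,
  exact ties downward, minimum 4.
* **Walk boundaries** are reflecting: a step into the wall is counted but
  leaves the walker in place. Encounters are *arrival events* at blob
  sites; a wall-rejected step is not a new arrival. Walkers may start on
  blob sites (an immediate encounter) or on the target (a zero-step
  search); both behaviours are switchable flags.
* **Centring** uses the integer offset $\lfloor(\mathrm{cell}-\mathrm{nucleoid})/2\rfloor$.
* **Conditional-time evaluation** is exact linear algebra on a 3×3 matching
  system with scaled unknowns (no overflow for any $x$); small-$x$ handling
  as described above.
* **Calibration** brackets $k_a\in[10^{-2},10^{12}]$ nm³/s and reports the
  achieved bound-fraction range if no root exists.
* **Degenerate inputs** error early with informative messages: $P_b=0$
  conditional times, $P_t=0$ success times, $P_b=1$ with $P_t=0$
  (non-terminating visits), $k_a=0$ searches (never found: detection is
  sliding-only).

## Validation strategy

Every closed form is checked against an independent brute-force oracle that
shares no code with the implementation: Euler–Maruyama walkers with per-step
binding for the radial problem (time step well inside
$k_a\rho\,\mathrm{d}t<0.1$, $\sqrt{6D_3\mathrm{d}t}<0.05R_g$, with a
step-halving stability check), a discrete 1D walk with killing for the
sliding problem, a sparse fundamental-matrix solve for the lattice walk, a
2-state absorbing-chain solve for the loop statistics, and the event-level
search simulation for the assembled formula — all within 3 Monte Carlo
standard errors on parameter grids. The test suite runs the stochastic
pieces at reduced sizes (3000–4000 walkers, 10-blob conformations in
8×5×5 cells, 3000 Monte Carlo snapshots) chosen so the whole suite completes
in a few minutes; the package defaults remain the production values
(10⁴ walkers, 10⁵ equilibration attempts, 3/5 conformations).

One approximation deserves a number: the effective-medium property (the
per-step blob-encounter rate should equal the blob occupancy of the cell
lattice) holds to about 2% relative for first-passage trajectories and to
better than 0.5% for return trajectories. The 2% offset is systematic, not
statistical — the exact fundamental-matrix solve shows the same value as the
simulation. Two small effects compound: the target blob is excluded from the
encounter count, and trajectories that end at the target under-sample the
blob-rich nucleoid core relative to the uniform measure. Ensemble means are
insensitive to the individual conformation (coefficient of variation ~2% at
mid-range rates), consistent with the effective-medium picture.

## Known limitations

* One-state searcher: no separate search/recognition conformations, so the
  model may slightly underestimate in vivo search times.
* Mean-level only: `mean_search_time()` returns expectations, not
  first-passage distributions (per-walker samples can be retained from the
  simulators for future distribution-level work).
* The homogeneous-coil density convention and the uncorrelated
  re-association assumption are idealisations of blob-internal structure.
* Very small sliding lengths combined with very small $P_b$ make individual
  conformations matter; the ensemble-mean treatment is least reliable there.
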