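---
title: "Synchronous Boolean attractors, phenotype annotation and cell fate maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synchronous Boolean attractors, phenotype annotation and cell fate maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macpol)
```

## The model

A Boolean network over nodes $x_1,\dots,x_n \in \{0,1\}$ with update rules
$f_i$ defines the synchronous map $F(x) = (f_1(x),\dots,f_n(x))$: all nodes
recompute simultaneously from the current state. Because $F$ is a function on
a finite set, the state space is a *functional graph* — every state has
exactly one successor — so every trajectory enters a terminal cycle. A cycle
of length 1 is a fixed point; longer cycles are cyclic attractors, and the
number of distinct states in the minimal cycle is its *period*. The *basin*
of an attractor is the number (or fraction) of initial states whose
trajectory ends in it; in exhaustive mode basins are exact and sum to $2^n$.

Assumptions worth keeping in mind: synchronous updating is a modeling choice,
not biology — it can create cycles that asynchronous schedules destroy, which
is precisely why this package exists (to take those cycles seriously rather
than discard them). Rules are parameter-free logic; no kinetics or
concentrations enter. Environmental signals (cytokines, hypoxia) are nodes
with the *identity* rule: they hold whatever value the initial condition
gives them, so "a monocyte in an IL-10 microenvironment" means "start with
IL10 = 1 and let it persist". This makes the attractor structure decompose by
input configuration, which is intended: each environment has its own
landscape.

## Rule files and state encoding

Two dialects are read and written: BoolNet-style `targets, factors` text, and
a JSON dialect that additionally supports explicit truth-table rules
(`{"regulators": [...], "outputs": [...]}`, output index built with regulator
1 as least significant bit) and per-node input policies (`"hold"`, `"0"`,
`"1"`). The expression grammar is `!`/`NOT`, `&`/`AND`, `|`/`OR`,
parentheses, constants `0`/`1`, with case-sensitive node names matching
`[A-Za-z0-9_]+`; names from the literature are normalized (NF-κB → `NFKB`,
IL-1β → `IL1B`). Rules are parsed by the package's own recursive-descent
parser — never by `eval(parse(...))` on raw file text — and serialized in a
canonical form (minimal parentheses), so serialize–parse–serialize is
byte-stable.

States are encoded as integers with the node at position 1 as the least
significant bit. Declaration order therefore matters and is preserved
end-to-end; canonical attractor identity (rotate the cycle so the smallest
code comes first) is what makes censuses and fate maps reproducible across
runs and entry points.

## Attractor enumeration

Exhaustive mode builds the full successor table by evaluating every rule
*vectorized over all $2^n$ states at once* ($O(n)$ vector operations), then
assigns every state to its attractor by following successors with memoized
path compression — each state is visited $O(1)$ times amortized. The default
ceiling is $n = 22$ (about 4M states; minutes on one core, configurable).
Above it, sampled mode draws initial states uniformly with an explicit seed
and follows each trajectory (batched, one synchronous step per iteration
across all unresolved trajectories). Sampled results are always a subset of
the exhaustive attractor set; the sample stream is sequential, so increasing
`n_samples` under the same seed never loses an attractor. An independent
oracle — per-state scalar evaluation plus pointer-doubling on the functional
graph — re-derives attractor sets and basins in the test suite; the two
routes share no code.

## Phenotype annotation

A `phenotype_scheme` is data: ordered labels, one marker condition per
non-fallback label, a fallback label, and an outcome class per label. The
default macrophage scheme is M1 ⇔ `STAT1 | NFKB`, M2a ⇔ `STAT6`, M2b ⇔
`AP1`, M2c ⇔ `STAT3`, M2d ⇔ `HIF1A`, fallback M0; M1 is tumor-eliminating,
the M2 variants tumor-promoting, M0 neutral. The literature is not fully
consistent about AP-1 (it is sometimes listed among M1 drivers, sometimes as
the M2b marker); the default follows the M2b reading, and because schemes are
plain JSON a user who prefers the other reading edits one line, not code.

A state takes *every* label whose condition holds (composite names like
`M1M2c` concatenate in scheme order); classification is purely structural:
`cycle` iff period > 1, else `pure fixed point` with exactly one label,
`hybrid fixed point` with two or more. Attractor names join per-state names
with `/` starting from the canonical rotation, so the same cycle discovered
from any phase gets the same name. Note that a period-4 cycle can carry a
label sequence of period 2 (`M0/M2c/M2c/M0` repeats labels while the
underlying states differ); the package reports state-level period and
label-level name independently and never collapses one into the other.

## Perturbations and the fate map

A perturbation is a *persistent clamp*: the node's rule is replaced by a
constant, modeling sustained knockout or activation, and the perturbed state
is followed to an attractor **of the clamped network**. (A one-step
`"transient"` flip in the original network is available for comparison, but
the maintained reading is the default and the primary contract.) Sign
convention: `+` means the node was off and is turned (and held) on, `-` the
reverse. For a cyclic source the perturbation is launched from *every* state
of the cycle — the union of destinations is phase-invariant, which removes an
arbitrary choice — and a node whose value varies across the cycle is clamped
both ways, flagged `original_value = "varies"`. Fate-map vertices are
annotated attractors; destinations are tagged with their clamp context
(`"STAT1=1"`), because an attractor of a clamped network is a different
object from a look-alike attractor of the original network. Everything is
deterministic, so exports (TSV, GraphML, DOT — all hand-written, byte-stable)
are identical across runs.

## Embedding

Attractor states (one row per state; a period-p cycle contributes p rows) are
embedded with exact t-SNE: squared Euclidean distances on the binary vectors
(equivalent to Hamming distance), per-point Gaussian bandwidths calibrated to
the target perplexity by bisection, then 1000 gradient-descent iterations
with early exaggeration (factor 4 for 100 iterations) and momentum
(0.5 → 0.8 at iteration 250), learning rate 100. Row counts here are tens,
so the $O(m^2)$ exact algorithm is appropriate; no approximation is used and
a fixed seed gives identical coordinates. Defaults: perplexity
`min(5, distinct rows - 1)` (shrunk with a warning if not below the distinct
row count), seed always explicit. Duplicate rows are removed before the
optimization and re-expanded afterwards with a deterministic jitter uniform
in a disk of radius 1% of the layout span, so coincident states stay visually
coincident without overplotting. Caution: t-SNE layouts are not comparable
across seeds or parameter settings; the embedding is a reading aid, not a
metric result, and per-attractor averaging (one point per attractor) is the
user's own aggregation choice on the returned coordinates.

## The synthetic data: what it emulates and what it does not

`random_nk_network()` draws the classic Kauffman ensemble — $k$ distinct
regulators per node, a uniform random truth table with output bias $p$ —
because uniform sampling is well defined over truth tables, not over
expression syntax; tables serialize natively in the JSON dialect and lower to
minterm DNF in BoolNet text. Defaults used throughout the tests are
$n \le 12$, $k \le 3$, bias 0.5: the regime where exhaustive enumeration is
instant and the oracle can be run on every network.

`analytic_fixture()` ships four networks with closed-form censuses (identity
nets, the toggle pair, the 3-node negation ring, a monotone AND ring whose
census was frozen once from brute force).

`macrophage_fixture()` is a 17-node network encoding the directed
interactions the macrophage polarization literature states in prose: IFN-γ
drives STAT1, IL-10/IL-6/TGF-β drive STAT3, IL-4/PPAR-γ/KLF4 drive STAT6,
TNF-α/IL-1β/GM-CSF drive NF-κB, IL-6/IL-1β drive AP-1; STAT6 represses the
M1 factors and AP-1, PPAR-γ feeds back negatively on AP-1, SOCS3 (induced by
STAT1, NF-κB and — classical JAK/STAT feedback — STAT3 itself) shuts STAT3
down, and hypoxia (HIF1α) switches on PPAR-γ and KLF4. The STAT3 → SOCS3 term
is the one edge beyond the verbatim prose: without that delayed negative
feedback the fixture has no cyclic attractors at all, and the
monocyte/regulatory oscillations the model family is known for (M0/M2c
cycles) depend on it. GM-CSF acting through NF-κB is an interpretation and is
marked as such in the fixture documentation.

What a green test on this fixture establishes: the pipeline's contracts —
exact enumeration, annotation logic, fate-map re-verification — on a network
with realistic structure (held inputs, repression hierarchy, one oscillator).
What it does **not** establish: agreement with the published census of the
original curated macrophage network, whose rules are not printed in the
source literature and are not redistributed here. The fixture's own census
(512 attractors: 169 fixed points, 343 period-4 cycles — one attractor per
configuration of the nine held inputs) is a *frozen regression surface*,
generated once by the independent oracle via `tools/make_snapshots.R` and
compared byte-for-byte in the tests; changing the fixture requires rerunning
that script deliberately.

## Numerical and design choices

* **Exhaustive ceiling 22**: $2^{22}$ integer successors plus the traversal
  fit comfortably in memory and minutes; beyond it the successor table
  dominates and sampling with an explicit seed is the honest mode.
* **Canonical forms everywhere**: cycles rotate to smallest integer code;
  serializers emit minimal-parenthesis expressions; exports sort nothing
  after construction (vertex ids are discovery-ordered, which is itself
  deterministic). This is what makes "two runs are byte-identical" a test
  rather than a hope.
* **Ties and degenerate inputs**: empty attractor sets summarize to zero
  counts; embedding refuses fewer than 3 distinct rows (plot those directly);
  clamping a node to its current value is a no-op by construction;
  `max_steps` below the trajectory's needs errors rather than returning a
  truncated "attractor".
* **Why no SAT/BDD back end**: the target networks (tens of nodes, held
  inputs) sit in the exhaustive/sampled regime; symbolic attractor detection
  is out of scope by design.
* **Acceptance**: the original study's headline numbers (27 attractors, 19
  fixed points, two period-2 cycles) require its unpublished rule set, so
  they are exposed as `validate_census()` for users who obtain those rules
  rather than asserted against the synthetic fixture — asserting them here
  would be fiction. All machine-checkable criteria are property-based and run
  in the test suite at full stated scale (100 random networks, seeds 0–99).

## Limitations

Only synchronous, deterministic updating is implemented; asynchronous
"complex attractors" and probabilistic schemes are out of scope. The
macrophage fixture is a stand-in, not a reconstruction: its fate map is
internally consistent but should not be quoted as the polarization map of any
published curated network. Sampled basin fractions are frequencies, with no
confidence machinery beyond the subset/monotonicity guarantees. t-SNE
coordinates have no units and no cross-run meaning.
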