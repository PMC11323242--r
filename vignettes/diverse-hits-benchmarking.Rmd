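---
title: "Counting diverse hits: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting diverse hits: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Goal-directed molecule generators propose molecules and receive feedback
from a scoring function (an "oracle", typically a QSAR bioactivity model).
Two failure modes plague naive comparisons of such generators. First, mode
collapse: a generator can flood the log with near-identical high scorers, so
counting raw hits rewards redundancy. Second, unbounded computation: a
method that needs millions of oracle calls is useless when each call is a
docking run. `divhits` measures what practitioners actually want: **how many
structurally distinct high-scoring molecules a generator finds under a fixed
computational budget**.

## The diverse-hits measure

A molecule is a *hit* when its raw oracle score reaches the threshold
$S$ (default $0.5$, the natural operating point of a probabilistic
classifier) and it passes the property filter. Given the set $H$ of hits,
the number of *diverse hits* is the #Circles measure

$$\mathrm{nCircles}_D(H) \;=\; \max_{C \subseteq H} \; |C|
\quad \text{s.t.} \quad d(x, y) > D \;\; \forall\, x \neq y \in C,$$

with $d$ the Tanimoto (Jaccard) distance between binary circular
fingerprints. Geometrically: the largest packing of circles of radius $D$
centered on hits such that no center lies inside another circle. Classical
alternatives fail here, and the package ships constructions that prove it
(`make_clustered_points()`): internal diversity — the mean pairwise
distance — is *maximized* by two distant molecules, is *inflated* by a few
tight clusters, and can *decrease* when a genuinely new molecule is added.
#Circles grows monotonically with real coverage and is indifferent to
duplication.

Finding the optimum is a maximum-independent-set problem on the "conflict
graph" connecting molecules at distance $\le D$, so the package provides
two solvers:

* `n_circles_exact()` — branch and bound over the conflict graph (greedy
  initial bound, branching on the highest-degree candidate, isolated
  vertices taken greedily). Exact but exponential; guarded at 25 items by
  default.
* `n_circles_greedy()` — sphere exclusion: scan items in a given order,
  keep an item iff it is farther than $D$ from everything kept. Yields a
  maximal packing, hence a lower bound on the exact count; with the scan in
  generation order the result is reproducible from a log and monotone along
  log prefixes, which is what the budget-sweep curves
  (`diverse_hits_curve()`) rely on.

Separation is strict ($d > D$ survives, $d = D$ conflicts): a pair exactly
at the threshold is counted once. With $D = 0$ the measure reduces to the
number of distinct fingerprints; with $D \ge \max d$ it is 1.

## Scoring: oracle × property filter × diversity filter

The score a generator sees is the product
`final = raw × [property filter] × [diversity filter]`.

* **Oracle** — any function mapping a molecule record to $[0,1]$. Outputs
  outside $[0,1]$ raise immediately ("broken oracle") rather than being
  clamped: a miscalibrated oracle invalidates a benchmark silently
  otherwise.
* **Property filter** — lenient medicinal-chemistry ranges, all closed
  intervals: MW $\in [157, 761]$ Da, logP $\in [-2.0, 8.3]$, and the
  fraction of idiosyncratic substructures $\in [0.00, 0.08]$. The
  idiosyncratic fraction is the share of a molecule's atom-centered
  circular keys (radii 0–2) absent from an explicit reference vocabulary;
  the vocabulary is a required input (`vocabulary_from_records()`) so any
  reference collection can define "ordinary chemistry". Violating any range
  zeroes the score.
* **Diversity filter (DF)** — a monotone memory of previously found hits
  (raw $\ge S$ with both filters passing). Any candidate within Tanimoto
  distance $D_{DF} = 0.7$ of a stored hit scores zero, which pushes
  generators out of already-solved regions. The memory stores every hit's
  fingerprint individually — the simplest faithful reading of "previously
  found hits"; bucketed or scaffold-keyed variants exist in the literature
  but add free parameters.

Two deliberate asymmetries: (1) hit *determination* in evaluation ignores
the DF — a genuine hit whose score was suppressed because a neighbor came
first still counts, which is the entire point of keeping a full audit log;
(2) the hit threshold is inclusive (raw $\ge S$). The boundary case has
probability zero for continuous oracles; inclusivity makes the discrete toy
oracles reproducible.

## Budgets, logging, determinism

`run_generator()` wraps any generator (a function receiving a scoring
callback, a budget view and a seed) and enforces one of two regimes:
a **sample limit** (max oracle calls, reference value 10 000) or a **time
limit** (max wall seconds, reference value 600). Design choices worth
knowing:

* **Duplicates are free.** Distinct canonical SMILES consume budget;
  repeated proposals are answered from a cache and logged but not charged —
  re-scoring a known molecule costs nothing in a real deployment. A strict
  counting mode (`strict_counting = TRUE`) exists for sensitivity analysis.
* **Invalid SMILES consume budget** and score zero: invalid generation is
  penalized, not hidden.
* **Virtual clock under the sample limit.** Time is irrelevant to that
  regime, and logging wall time would make reruns differ byte-for-byte; so
  sample-limited logs carry `elapsed_seconds = 0` and identical
  (generator, seed, oracle) runs write identical CSVs. Time-limited runs
  log real wall time, the budget check runs between proposals (so a batch
  may overshoot), and `evaluate_log(time_cutoff = …)` truncates post hoc at
  exactly the cutoff, making reported results overshoot-free.
* One master seed fans out to named streams (`derive_seed()`), so the
  generator's randomness is decoupled from anything else.

Logs are seven fixed columns (`call_index`, `elapsed_seconds`,
`canonical_smiles`, `raw_oracle`, `property_pass`, `df_pass`,
`final_score`), serialized with 17 significant digits so the CSV round-trip
is bit-exact. Every reported number is recomputable from the log alone.

`aggregate_runs()` reproduces the benchmark's reporting convention: per
generator × task the min/median/max diverse-hit count over seeds, ranks
within each task by median (ties share the mean rank), generators ordered
by average rank across tasks. The median as central tendency is our choice;
ranges are reported alongside.

## Chemistry backend and fingerprints

OpenBabel (via ChemmineOB) performs all chemical perception: SMILES
parsing, canonicalization, molecular weight and logP. Malformed SMILES are
first-class values (`valid = FALSE`), never exceptions.

Fingerprints are binary folded circular fingerprints computed by the
package from the OpenBabel-kekulized molfile graph: the radius-0 atom
invariant combines atomic number, heavy-atom degree, bond-order sum and
formal charge; each iteration hashes the sorted (bond order, neighbor key)
list into the center's key — the Morgan update. Radius 2 and 2048 bits are
the community-default ECFP4-class settings; both are configurable
(`fingerprint_config()`), the bit width must be a power of two (folding),
and a count-fingerprint variant exists but the binary form is the reference
path. Computing the keys in the package rather than taking a fixed-width
backend fingerprint buys three things: configurable radius/width, the
unfolded per-atom keys that the idiosyncrasy filter consumes, and an
order-of-magnitude faster scoring loop. Graphs are always built from the
*canonical* SMILES, so fingerprints and keys are
canonicalization-invariant by construction (kekulization depends on the
written form).

Bemis–Murcko scaffolds are computed by iteratively deleting terminal heavy
atoms from the molfile graph and re-canonicalizing the pruned molfile;
exocyclic substituents (including double-bonded ones) are stripped, and all
acyclic molecules share one empty-scaffold class.

## The synthetic fixtures

`make_library()` enumerates decorated ring scaffolds (10 scaffold classes ×
22 substituents at one or two positions, ~2 650 candidates), shuffles the
enumeration with a seed and keeps the first *n* unique valid molecules.
This emulates the *structure* of a screening collection — clustered by
scaffold family, MW roughly 90–600 Da so the property filter genuinely
rejects some members — but not its scale or its pharmacology. The toy
oracle (`make_toy_oracle()`) scores a molecule as
$\max_i \mathrm{sim}(x, a_i)^{k}$ over a set of active seeds: it
reproduces the *contract* of a bioactivity classifier (deterministic,
probabilistic output, threshold-0.5 hit semantics) and, being
similarity-based, makes the diversity filter demonstrably force
exploration. It does not emulate any real activity landscape —
activity cliffs, assay noise and multi-site binding are absent — so
passing tests demonstrate the correctness of the *harness arithmetic*, not
performance on real targets. `make_benchmark_task()` picks the actives by
MaxMin among filter-passing library members, so the actives span scaffold
families and "diverse hits" is a meaningful quantity.

## Reference generators

The two virtual-screening baselines propose a library permutation — uniform
random, or MaxMin-ordered (`maxmin_order()`, start fixed at index 1 for
reproducibility; ties by smallest index). The mutation GA keeps the best
scorers seen, samples parents rank-weighted ($0.85^{\mathrm{rank}}$), and
applies local SMILES edits: atom substitution within aromaticity class,
chain-atom insertion/deletion, and substituent-branch insertion/deletion
from a small fragment list, with up to 10 validity retries and a parent
fallback. It is a harness-exercising reference, deliberately simple, not a
reproduction of any published generator. A stagnation guard ends a run
after 25 consecutive batches that consume no budget — with
`mutation_rate = 0` every offspring is a cached duplicate and the run
would otherwise never terminate under a sample limit.

## Problem sizes used by the tests and the acceptance script

The test suite checks the exact #Circles solver against exhaustive
enumeration over all $2^n$ subsets on 210 random instances ($n \le 12$,
$D \in \{0.3, 0.5, 0.7\}$), monotonicity along 50 nested chains
($n \le 15$), and the full pipeline on libraries of 150–600 molecules at
budgets of 60–800 calls. The acceptance script builds a 600-molecule
library and screens it at a 300-call budget — the budget is a fraction of
the library, the regime where proposal order matters, which is the
scaled-down analog of screening a multi-million-compound collection at ten
thousand calls. The GA-versus-random comparison disables the diversity
filter and places the actives outside the screening library: random
screening is then capped at the library's best similarity while a
feedback-using method can climb past it; with the DF on, the harness's
point is precisely that exploitation is penalized, and diverse-hit
comparisons there favor the spread-out screeners.

## Known limitations

* OpenBabel's leniency defines validity: some unusual-valence structures
  parse that stricter toolkits would reject.
* The exact solver is for small hit sets (post-deduplication evaluation
  switches to greedy above 25 hits), so large-log evaluation is a greedy
  lower bound — consistent with how the measure is used for reporting.
* Distances live on binary fingerprints; stereochemistry, 3D shape and
  count information are outside the default path.
* The idiosyncrasy filter is a declared stand-in: same range semantics as
  published property filters, but the substructure vocabulary is supplied
  by the user (or the fixture library), not by any curated collection.
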