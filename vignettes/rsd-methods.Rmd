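---
title: "Reciprocal smallest distance orthology: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reciprocal smallest distance orthology: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsdlite)
```

This vignette is the package's account of the science it implements: the
models and their assumptions, the tunable parameters and why their defaults
are what they are, what the simulator does and does not emulate, and the
design choices made where the design was genuinely open.

## The decision procedure

RSD calls a pair (*i*, *j*) orthologous between genomes *I* and *J* when
*j* is the smallest-ML-distance hit of *i* in *J* **and** *i* is the
smallest-ML-distance hit of *j* in *I*. The reciprocal requirement is what
distinguishes it from one-directional best-hit methods: a recent paralog
*p* of *i* (duplicated after the speciation) sits at distance ≈ t + t_dup
from *j*, strictly beyond the true ortholog at t, so the reciprocal pass
from *j* lands on *i*, not *p*, and the pair (*p*, *j*) is rejected. Using
distance rather than alignment score matters because score conflates
divergence with length and composition; a maximum-likelihood distance under
an explicit substitution model is a consistent estimator of divergence.

Two asymmetries in the procedure are intentional and follow the classical
formulation. First, the reciprocal pass reuses exactly one number from the
forward pass — the cached *i*–*j* distance — and computes every other
candidate's distance fresh. Second, each query contributes at most one pair
per parameter setting, while a subject may be claimed by several queries
(many-to-one calls are legitimate under gene loss).

Tie handling is deterministic: in the forward direction a distance tie goes
to the lexicographically smallest subject id (reproducibility); in the
reciprocal direction a tie that *includes* the original query counts as
confirmation, so a genome containing two identical copies of a gene cannot
destroy the self-evident pair.

## Search: exact Smith–Waterman with Karlin–Altschul E-values

The search stage computes the optimal local alignment score of the query
against every database sequence (affine gaps: a gap of length k costs
`gap_open + k * gap_extend`) and converts scores to E-values

E = K · m · n · exp(−λS),

with m the query length and n the **total residue count of the database**
(the convention of protein search tools, so thresholds transfer across
database sizes). λ is solved from Σᵢⱼ πᵢπⱼ·exp(λ·sᵢⱼ) = 1 at scheme
construction; a matrix whose expected score under the background
frequencies is non-negative is rejected there, because the E-value theory
requires negative drift. Defaults are BLOSUM62 with gap penalties 11/1 —
the standard protein-search defaults — uniform background frequencies, and
K = 0.13 (the classical ungapped BLOSUM62 prefactor).

Two deliberate approximations are documented rather than hidden. The
*ungapped* λ and K are applied to *gapped* scores, and no heuristic seeding
is used (every score is exact). The resulting E-values are conservative in
absolute terms but strictly monotone in score, which is all the algorithm
needs: the threshold stays a tunable knob, and the score itself is exact,
unlike a heuristic seeded search. The scan returns at most `max_hits`
(default 20) hits; RSD only ever uses the near-smallest-distance
candidates, and the cap is lifted (`max_hits = Inf`) where exactness
matters, e.g. in the stored-table phase and the monotonicity tests.

The ambiguity code `X` is accepted on input, scores 0 against everything in
search, and is treated as missing data (column excluded) in distance
estimation. Stop characters `*` are stripped on read with a warning; the
rare codes B/Z/J/U/O are mapped to `X`.

## Global alignment and the divergence filter

Candidate hits are globally aligned to the query (Needleman–Wunsch, same
scoring scheme, terminal gaps penalized) and kept when the *alignable
fraction* — columns with residues in both rows over total columns — is at
least the `divergence` parameter. The filter discards fragment matches and
domain-only hits whose local alignment is strong but which cover too little
of either protein for a whole-protein distance to be meaningful. Traceback
ties prefer substitution columns over gaps in the first sequence over gaps
in the second, making alignments byte-reproducible across runs.

## ML distance under an empirical model with gamma rates

The estimator maximizes, over t ∈ [0, t_max],

L(t) = ∏over ungapped columns πₐ · (1/K) Σₖ P(a→b | t·rₖ),

where P(·|τ) = exp(Qτ) with Q the empirical rate matrix (`"JTT"` default;
`"Dayhoff"` and the equal-rates `"Poisson"` model are included, the latter
because its distance has the 20-state Jukes–Cantor closed form
t = −(19/20)·ln(1 − (20/19)·p̂), used as an internal oracle). Q is built
from exchangeabilities and stationary frequencies as Q_ij = S_ij·π_j,
rescaled to one expected substitution per site, and eigendecomposed once
through the reversible symmetrization, so each likelihood evaluation is two
20×20 products per rate category. The JTT and Dayhoff exchangeabilities and
frequencies are taken from the phangorn phylogenetics package, the standard
R carrier of these published matrices.

Rate heterogeneity uses Yang's discrete-gamma construction: K
equal-probability categories (default K = 4, the convention), each at the
*mean* of its gamma(α, α) slice, renormalized to average exactly 1. α
defaults to 1.0 and is a per-run parameter: the appropriate value depends
on the phylogenetic depth of the comparison, and no automatic mapping from
depth to α is attempted — choosing one is the user's modeling decision.
`alpha = Inf` or `K = 1` disables heterogeneity.

Numerical choices: columns containing a gap or `X` in either row are
excluded (complete-column deletion); zero usable columns is an error that
distinguishes an all-gap overlap from an all-ambiguous one. Optimization is
a coarse bracketing pass (t = 0 plus 60 log-spaced points) followed by
Brent's method in the winning bracket, with explicit re-checking of the
t = 0 endpoint; tolerance 1e-6 on t. The likelihood in t is unimodal for
this family of models in practice; the bracketing pass protects against
plateau artifacts at extreme divergences. t_max defaults to 20
substitutions/site and estimates at the boundary are flagged
`converged = FALSE` rather than silently returned.

## The parameter grid

Production orthology resources run RSD across a grid of
(divergence, E-value) settings from conservative to relaxed, because no
single setting suits both closely and distantly related genome pairs.
`param_grid()` defaults to {0.2, 0.5, 0.8} × {1e-20, 1e-15, 1e-10, 1e-5} —
12 combinations, the conventional grid size. The classical published
examples (0.8, 1e-10) sit inside it. The specific 12 production values are
not published; these placeholders span the documented conservative-to-
relaxed range and are fully user-overridable.

## Two-phase execution model

Searching is cheap per pair but universal; distance estimation is the
expensive, setting-dependent step. The workflow therefore splits: phase 1
runs every ordered genome pair once at the *most relaxed* E-value of the
grid and persists untruncated hit tables in the store
(`blast_result/`); phase 2 — possibly in a different process, possibly
repeated — reads only the store, filters each table down to its setting's
threshold, and writes one ortholog table per (pair, setting)
(`ortholog_results/`). Storing untruncated, relaxed-threshold tables is
what makes the stored route *exactly* equivalent to on-the-fly searching
for every tighter setting; the equivalence is asserted in the tests.

The executor emulates the contract of a streaming map framework with
logical workers inside one process: a runner file of command lines is the
unit of input, one map task per line; each success writes a `part-%05d`
file (no reducer — the part files are the final output); failures retry up
to `max_attempts` (default 4), preferring a different worker; a worker
accumulating `blacklist_threshold` consecutive failures (default 4) is
removed from the pool; if all workers are gone the run aborts carrying the
partial reports. The per-task timeout (default 86400 s, a value chosen in
production practice to separate genuinely long-running genome pairs from
hung jobs) is cooperative — it interrupts R evaluation, not blocking
foreign calls. Speculative re-execution defaults off, matching practice for
workloads whose task durations vary over orders of magnitude; when enabled
it is emulated post hoc: an attempt slower than twice the median of
completed tasks is re-run once elsewhere and the faster result wins. A
single-process emulator cannot observe a task mid-flight, so "duplicate a
running straggler" becomes "re-run a finished straggler"; the scheduling
effect on reports is the same.

Runner-file command grammar (the classical systems show none, so this
package defines one):

```
rsd-blast --query-genome A.aa --db-genome B.aa --evalue 1e-05
rsd-ortho --genome-a A.aa --genome-b B.aa --divergence 0.8 --evalue 1e-10
```

whitespace-separated with no shell interpretation, so lines are parseable
exactly as a streaming mapper reads them. Genome and sequence ids are
sanitized to `[A-Za-z0-9_.-]` on ingest for the same reason; the exact
offending-character set is a convention of this package.

## The workload planner

`process_count()` implements f(N, O, M) = (N·O + N(N−1)/2)·M: one process
per compared pair per setting, where N genomes are new and O were already
processed (existing genomes are never re-compared among themselves).
`total_job_count()` adds the search phase at two tasks per pair (both
directions). Both conventions for the search count are reported — the
bidirectional task count that the runner generator actually produces, and
the unordered new-vs-existing cross-pair count that summaries sometimes
print — because both appear in practice and they differ by more than a
factor of two. `time_projection()` divides serial core-hours by available
cores; `instance_cost()` rounds to whole dollars. The bundled instance
table reproduces the constant-work pattern that makes per-core-equivalent
pricing come out equal across instance shapes.

## What the simulator emulates — and what it does not

`simulate_genome_pair()` draws each family's ancestral sequence from the
model's stationary frequencies with per-site discrete-gamma rates, evolves
two copies independently for t/2 each, optionally adds (a) recent paralogs
— a duplicate of the genome-A copy evolved a further `t_dup`, with at least
one substitution enforced so the duplicate is distinguishable — and (b)
unrelated singletons drawn fresh from the stationary distribution. Defaults
(100 families, lengths uniform on 100–400 residues, t = 0.3, α = 1) are
chosen as a realistic mid-range bacterial-proteome divergence scenario:
deep enough that raw-score shortcuts are unreliable, shallow enough that
the search step retains essentially all true pairs.

Deliberately absent: indels within families (sequences of a family stay
equal length), so the simulator stays exactly inside the estimator's model
and parameter-recovery tests are clean; the divergence filter is instead
exercised with constructed fragment fixtures. Also absent: gene birth/death
dynamics, domain shuffling, composition bias, and genome rearrangement.
Consequently, passing tests demonstrate the correctness of the decision
procedure and estimator under their own model assumptions — they do not
certify performance on real proteomes, where alignment error and domain
architecture add failure modes the model does not contain.

One property of the model is worth stating precisely: "RSD rejects recent
paralogs" is an *almost-sure* statement, not an absolute one. A paralog's
extra substitutions occasionally revert mismatch sites toward the other
genome's ortholog, making the paralog genuinely closer in expected
distance — at which point RSD, correctly applying its own criterion,
confirms it. The probability decays rapidly with `t_dup`·length (it needs
the few extra substitutions to be dominated by back-mutations); at the
default conditions it is negligible, but it is a property of sequence
evolution, not an implementation artifact.

## Problem sizes used in the validation suite

The test suite validates the arithmetic exactly (planner, cost model,
runner-file counts at the 55-new/399-existing production scale), the
aligners against brute-force DP oracles (100 random pairs ≤ 40 residues,
plus an external cross-check against Biostrings' aligner), the estimator
against the Jukes–Cantor closed form (2000 sites), a 2000-point grid-search
oracle (50 random alignments), an external phylogenetics implementation
(phangorn's `dist.ml`), and parameter recovery (200 replicates × 2000 sites
at t ∈ {0.1, 0.5, 1.0}, mean within 5%). End-to-end recovery runs 10
simulated 100-family genome pairs at t = 0.3 (sensitivity ≥ 0.95,
precision 1.0) plus paralog-rejection fixtures at the generator defaults.
These sizes complete in a few minutes on one CPU while leaving the
Monte-Carlo assertions comfortable margins.

## Known limitations

- E-values use ungapped Karlin–Altschul parameters on gapped scores;
  absolute E-values are shifted relative to gapped-calibrated tools (order
  preserved). A raw-score threshold mode is available where exactness
  matters.
- The estimator is pairwise-only by design: no tree likelihoods, no
  standard errors on t̂, no among-pair sharing of α.
- The executor emulates scheduling semantics (retry, blacklist, timeout,
  part files, resumability), not distribution: workers are logical, within
  one process.
- No nucleotide input or translation; proteomes only.
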