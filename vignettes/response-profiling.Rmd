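---
title: "Methods: agreement networks and conceptual profiles from multiple-choice responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: agreement networks and conceptual profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respnet)
```

# The problem

Multiple-choice physics assessments such as the Force Concept Inventory
(FCI) are built around distractors that encode common misconceptions:
which wrong answer a student picks is as informative as whether they were
right. Prior distractor-analysis work has shown that incorrect options are
not chosen independently — certain (question, option) pairs are selected
jointly, forming *conceptual modules* that correspond to coherent
non-Newtonian ideas (the impetus force, confusion about gravitational
action, and so on). Given a cohort's response table, this package asks:
which students answer *like each other*, and what mixture of conceptual
modules characterizes each such group's errors?

The pipeline has five stages:

1. **Bipartite projection.** The response table becomes a binary
   students-by-(question, option) incidence matrix $M$, and the one-mode
   projection $A = M M^\top$ (diagonal zeroed) counts, for every pair of
   students, the number of questions answered identically. With 9
   questions, weights run from 0 to 9. A missing response contributes to
   no agreement count; zero-agreement pairs are non-edges rather than
   zero-weight edges.

2. **Backbone extraction.** $A$ is dense and mostly noise: any two
   students agree somewhat by chance. We keep only locally significant
   edges using a nonparametric, locally adaptive rule: each node ranks its
   incident edges by *fractional weight* $w_{ij}/s_i$ (edge weight over
   node strength), and the p-value of an edge at that endpoint is the
   fraction of the node's incident edges with strictly greater fractional
   weight — one minus the empirical CDF under the
   $\le$ convention. An edge survives at level $\alpha = 0.01$ if it is
   significant from **either** endpoint (the `both` rule is available as an
   option). The rule is parameter-free and scale-invariant, and because
   ties share a p-value of zero, a node whose incident weights are all
   equal keeps all of them — the method never manufactures sparsity where
   the data are genuinely uniform.

3. **Community detection.** Students are partitioned by minimizing the
   two-level map equation
   $L = q\,H(Q) + \sum_c p_c^\circlearrowright H(P^c)$,
   the expected per-step description length (bits) of a random walk
   encoded with one index codebook over communities and one codebook per
   community. Visit rates are strength-proportional
   ($p_\alpha = s_\alpha / 2W$), the standard undirected simplification —
   no teleportation, which is a directed-graph necessity only. The
   optimizer is a greedy two-phase search (local moves, then aggregation,
   repeated to convergence) restarted from seeded shuffled node orders;
   the best of `n_trials = 100` restarts is kept and ties go to the first
   found. Weighted Newman–Girvan modularity
   $Q = \sum_c [w_{in}(c)/W - (s_c/2W)^2]$ is reported for the resulting
   partition as a descriptive statistic; it is never itself optimized.

4. **Motion screening.** When the cohort was scanned, per-run framewise
   displacement (FD, mm) is compared across *normative groups*
   (communities with $\ge 10$ members) by one-way ANOVA; while the
   omnibus test is significant, any group that Tukey HSD flags as having
   significantly greater FD than **each** remaining group is excluded and
   the test repeats. A single pass equals the iterated rule when exactly
   one group is inflated, which is the situation the screening is designed
   to catch.

5. **Conceptual profiles.** For each retained group we count incorrect
   responses falling in each catalog module. "Scaled by group size" admits
   two readings, so both are reported: `scaled_overlap` (responses per
   student, comparable across group sizes) and `share` (fraction of the
   group's incorrect responses, describing error composition). Shares sum
   to at most one; the remainder is unaffiliated distractors.
   `classify_profile()` calls a module *dominant* above a configurable
   share threshold (default 0.5) and labels profiles concentrated versus
   fragmented, alongside a normalized-entropy fragmentation index.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.01 | per-endpoint edge significance level for the backbone |
| `rule` | `"either"` | endpoint combination rule (`"both"` is stricter) |
| `min_group_size` | 10 | community size from which a group is "normative" |
| `n_trials` | 100 | seeded restarts of the map-equation search |
| `tolerance` | 1e-10 bits | minimum codelength gain to accept a move |
| screening `alpha` | 0.05 | omnibus and post hoc significance level |
| `dominance_threshold` | 0.5 | share above which a module dominates a profile |

`alpha = 0.01` and the normative threshold of 10 are the analysis's
substantive choices; the remaining values are numerical plumbing whose
variation within reason does not change results (the search is restarted
until the codelength stops improving well before 100 trials on cohorts of
this size).

# Numerical choices

* **Ties in the backbone.** Integer agreement counts produce many tied
  fractional weights. We count *strictly greater* weights, so tied-maximal
  edges get p-value 0 and are retained. Tie conventions change backbones;
  this one is stated explicitly and the `both`/`either` rules are both
  available because the choice cannot be recovered from first principles.
* **$0 \log 0 = 0$** throughout the map equation; an all-isolate graph has
  no defined walk and is an error, while isolated nodes in an otherwise
  connected graph get visit rate 0, become singleton communities, are
  excluded from $L$, and still count toward normative-group sizes, so
  every student stays accounted for.
* **Determinism.** All randomness (simulation, restart order) is driven by
  explicit seeds; identical configuration and seed reproduce byte-identical
  pipeline outputs, which the test suite asserts via checksums.
* **Degenerate statistics.** Identical observations give $F = 0, p = 1$;
  zero within-group variance with unequal means gives $p = 0$ with a
  `degenerate` flag rather than an error; paired comparisons with
  zero-variance nonzero differences likewise flag degeneracy.

# What the synthetic generator emulates

Real deposited response data are not required anywhere: the
`synthetic_data` functions generate cohorts with *planted* structure so
that every stage can be verified by recovery. The default configuration
reproduces the scale of the motivating study: 107 students, 9 in-scanner
FCI questions with 4 options, a 9-module catalog, and planted groups
whose accuracy rates (77%, 73%, 53% for the three target groups, ~61%
cohort mean) match the published behavioral summaries. The population
comprises 12 groups: the three target groups (24/17/10 students; one
coherent single-module profile, one two-module profile, one fragmented
three-module profile), a 12-student group with head motion inflated by
+0.2 mm mean FD (SD 0.05 mm, 3 runs per student), and eight background
groups of 5–6 students, each organized around one signature module.

Two generator design points deserve explanation:

* **Question-concentrated errors.** A first design drew each answer
  correct with a *uniform* per-question probability. That cannot separate
  two groups whose accuracies differ by a few points: their agreement is
  dominated by jointly correct answers, and the within- versus
  between-group agreement gap is a fraction of its own standard deviation.
  Real misconception-driven answering does not look like that either — a
  student holding the impetus misconception consistently misses the
  impetus questions. The generator therefore concentrates each group's
  error mass (odds ratio `difficulty_ratio`, default 40) on a small set of
  *hard questions* drawn from the group's dominant modules, while scaling
  rates so the group's mean accuracy equals `p_correct` exactly in
  expectation. This yields the banded, near-prototypical response heat map
  that real cohorts show, and it is the sense in which groups are
  "strongly separated" in the recovery benchmarks.
* **Collision-aware hard-question allocation.** Twelve groups share nine
  modules, and two groups that are both near-deterministically wrong on
  the same question *with the same option* become indistinguishable there.
  Hard-question sets are therefore allocated greedily — larger groups
  first, each preferring unclaimed (question, option) pairs, spreading
  across its modules, and extending to uncontested questions outside its
  module coverage when its quota exceeds what the catalog offers. The
  allocation is deterministic given the catalog, so the planted truth is
  reproducible.

What the generator does **not** emulate: real per-question difficulty
shared across all groups, partial knowledge (students mixing two
conceptions), response-time structure, missing answers under time
pressure, and any dependence between head motion and behavior. Passing
recovery tests therefore demonstrates that the pipeline recovers structure
of the planted kind at the study's scale and noise level — not that any
particular real cohort contains such structure.

Group profiles in the default population follow the published spectrum
qualitatively (coherent, two-module, fragmented) but not module-for-module:
the published group B shares its main module with group A, and planting
that overlap makes the two groups' wrong answers collide on identical
options, which no method operating on agreement counts could undo. The
defaults give each group an identifiable signature instead; the open
question of how strong between-group similarity is in real data is exactly
that, and the simulation is a test instrument, not a claim about the data.

The motion screening simulation uses the +0.2 mm shift (4 standard
deviations of the run-to-run spread) as its planted confound. This is a
deliberately clear-cut confound for verifying the exclusion logic; power
at subtler shifts falls off as usual for ANOVA at these group sizes.

# Problem sizes in the verification suite

The test suite checks the projection against a nested-loop counter on 200
random matrices (up to 12 students), the backbone against a brute-force
empirical-CDF evaluator on 100 random graphs (up to 15 nodes), the
map-equation search against exhaustive enumeration of all set partitions
on 50 random graphs (up to 8 nodes, Bell(8) = 4140 partitions each), the
ANOVA/Tukey stack against the reference implementations and a
2000-replicate null calibration, the motion screening against 500
planted-confound replicates, and planted-group recovery on 100 simulated
cohorts at the full 107-student scale, requiring a median adjusted Rand
index of at least 0.9. These sizes make every oracle exact or
statistically decisive while keeping a full run of the suite within a few
minutes.

# Known limitations

* The two-level (flat) map equation is implemented; hierarchical and
  overlapping variants are out of scope, as are directed walks.
* The backbone offers exactly the two endpoint rules; no global
  thresholding or multiple-testing correction across edges is applied,
  matching the fixed $P < 0.01$ analysis choice.
* Group profiles require the module catalog as an *input*; re-deriving
  conceptual modules from answer co-selection is a separate analysis this
  package deliberately does not perform.
* With 9 questions the agreement weights take only 10 values; backbones
  are tie-heavy, and partitions at the margins can differ between
  equally-scoring optima. The seed policy makes any such choice
  reproducible rather than unique.

# A worked run

```{r, eval = FALSE}
library(respnet)
out <- run_pipeline(seed = 42, out_dir = "run")   # simulate + analyze
glance(out$partition)      # communities, codelength, modularity
out$screen$report          # FD ANOVA audit trail
tidy(out$profiles)         # per-(group, module) overlap table
autoplot(out$partition, responses = out$responses)  # community heat map
autoplot(out$profiles, metric = "share")            # profile bar charts
```
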