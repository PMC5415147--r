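---
title: "Community detection as a game: model, search and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community detection as a game: model, search and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmneo)
```

## The community detection game

Given an undirected simple network $G = (V, E)$ with $n$ nodes, consider
the game in which every node is a player and a strategy profile
$s = (C_1, \dots, C_n)$ assigns each node a community label. The fitness
of a node set $C$ is the fraction of its members' link ends that stay
inside the set,

$$f(C) = \frac{\sum_{j \in C} k^{in}_j}
             {\bigl(\sum_{j \in C} (k^{in}_j + k^{out}_j)\bigr)^{\alpha}},$$

and the payoff of node $i$ is its marginal contribution to its own
community $\mathcal{C}_w$, $w = C_i$:

$$u_i(s) = f(\mathcal{C}_w \cup \{i\}) - f(\mathcal{C}_w \setminus \{i\}).$$

A partition from which no node can profitably defect — a Nash equilibrium
of this game — is taken as the community structure. The model's
assumptions are worth stating plainly: the network is simple, undirected
and unweighted; communities are disjoint (a node holds exactly one
label); and $\alpha$, which penalizes large communities through the
denominator, is fixed at 1, the value under which $f \in [0, 1]$ and all
the package's hand-checkable rationals hold. Degenerate sets are given
fitness 0 by convention: the empty set, and any set whose members are all
isolated, have a zero numerator, and we take the continuous limit
$f = 0$ rather than leaving $0/0$ undefined. A direct consequence worth
knowing: a node alone in its community always has payoff 0, and an
isolated (degree-0) node never changes any community's fitness.

## The reduced ascendancy relation

Nash equilibria of games with $n$ in the hundreds and payoffs without
convenient analytic structure are found by direct search, which needs a
way to *compare* two candidate profiles. The ascendancy operator

$$k(s, q) = \mathrm{card}\{\, i \mid u_i(s) \le u_i(q_i, s_{-i}),\;
  s_i \ne q_i \,\}$$

counts the players that would (weakly) gain by switching from $s$ towards
$q$; $s$ *ascends* $q$ when $k(s,q) < k(q,s)$, and profiles not ascended
by any other coincide with the equilibria whenever equilibria exist. The
reduced operator $k_p$ applies the same rule to a random subset $I_p$ of
$n_p = [p \cdot n]$ players only ($p \in (0,1]$, $n_p \ge 1$ enforced),
at most $4 n_p$ payoff evaluations per comparison. Three exact identities
make the reduction sound, and all three are enforced in the test suite by
exhaustive enumeration on small games:

* summed over **all** subsets of size $n_p$,
  $\sum_{I_p} k_p(s,q,I_p) = \binom{n-1}{n_p-1}\, k(s,q)$;
* the same identity nested inside any larger fixed subset;
* an equilibrium is never ascended under **any** subset, and the set of
  profiles non-ascended under the reduced relation is contained in the
  non-ascended set of the full relation.

Two readings of the published procedure are genuinely ambiguous, and both
are implemented behind flags rather than guessed:

* **Tie handling.** The set definition counts payoff *ties* as
  improvements ($\le$), while the procedural pseudocode increments on
  strict inequality. The default is $\le$, because the correctness
  results above are proved for it; `tie = "strict"` reproduces the
  procedural reading.
* **Subset sampling.** "Randomly select a node, $n_p$ times" admits
  with-replacement sampling; the formal definition of $I_p$ is a *set*.
  The default samples without replacement; `subset_replace = TRUE` gives
  the other reading.

Payoff comparisons are exact floating-point comparisons, deliberately
without an epsilon: community-game payoffs are ratios of small integers,
ties (e.g. symmetric nodes) are exact, and an epsilon would silently
change the counts that the worked example pins down.

## The search

`pmneo()` evolves a population $P$ of $M$ partitions and an archive $A$
of per-individual bests. Each individual owns a fixed community-count
budget drawn from $[C_{min}, C_{max}]$, so the population hedges over the
unknown number of communities; when a designated count is supplied
(`pinned_count`), a quarter of the population (`pinned_fraction = 0.25`)
is pinned to it. One generation, per individual: the $\ell$ nodes with
the lowest payoffs are each reassigned a *different* random label from
the budget (extremal optimization — always replace the worst components);
the offspring replaces the archive partner if it p-Nash ascends it under
one freshly drawn subset used for both directions of the count; the
population slot always takes the offspring, so $P$ explores while $A$
retains. Payoff ties in the worst-$\ell$ selection are broken uniformly
at random — on regular graphs many payoffs coincide exactly and a
deterministic tie-break would bias low node indices.

The mutation size follows a linear decay
$\ell = \max\{1, \mathrm{round}(0.1\, n\, (1 - g/G))\}$ from roughly
$n/10$ down to single-node refinements. The printed source for this
schedule is typographically corrupted; the implementation keeps the two
legible anchors (the $n/10$ leading factor and the $\max\{1,\cdot\}$
floor) and interpolates linearly in the generation count — the schedule
is injectable (`ell_schedule` argument) for anyone wanting to experiment
with alternatives.

As a diversity mechanism the search alternates $\Lambda = 30$ generations
on the original network with $\lambda = 10$ on a *mixed* copy:
$\mathrm{round}(\rho m)$ double-edge-swap attempts ($\rho = 0.02$), each
rejected if it would create a self-loop or duplicate edge, so the mixed
network is simple with the exact same degree sequence. At every phase
switch the archive alone is re-initialized (the pseudocode re-initializes
only $A$; the population carries its progress) and all payoffs are
re-evaluated on the newly active network. Offspring/archive comparisons
always use the active network. The final answer is the archive member
with the best modularity

$$Q = \frac{1}{2m}\sum_{ij}\Bigl(A_{ij} - \frac{d_i d_j}{2m}\Bigr)
      \delta(C_i, C_j)$$

computed on the *original* network — the solution must describe the real
network, not the perturbed one — with the sum over ordered pairs
including $i = j$ (the standard convention; the alternative
unordered-pair reading would halve the degree-product term and disagree
with published benchmark values; the implementation is cross-checked
against igraph's). Modularity is never used to guide the search.

Every payoff evaluation performed *inside* an ascendancy comparison is
counted and reported (`eval_count`): this is the quantity the reduction
is designed to shrink, and on identical seeds it is strictly smaller for
$p = 0.25$ than for $p = 1$. Payoffs computed once per generation for the
worst-node selection are not part of this count — they are incurred
identically at every $p$.

### Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `p` | 0.25 | fraction of players per comparison subset, $(0,1]$; $[p\,n] \ge 1$ required |
| `pop_size` (M) | 50 | population = archive size |
| `max_gen` | 500 | EO generations |
| `rho` | 0.02 | swap attempts per mixing event, as a fraction of $m$ |
| `lambda_big`, `lambda_small` | 30, 10 | generations per original / mixed phase |
| `c_min`, `c_max` | 2, 10 | community-count budget range (set to bracket the expected count) |
| `pinned_fraction`, `pinned_count` | 0.25, none | share of individuals pinned to a designated count |
| `alpha` | 1 | fitness exponent |

The continuous variant `pmneo_minus()` (no mixing phases — the Cournot
game has a unique equilibrium, so diversity restarts add nothing) mutates
the $\ell$ worst-profit firms by fresh uniform draws from the strategy
bounds, mirroring "assign another random community"; a Gaussian
perturbation is available behind `mutation = "gaussian"`. Its default
population of 10 applies to both $P$ and $A$ (the published setup names
one population size; the paired structure requires the archive to match).

## What the synthetic benchmarks do and do not show

`generate_gn()` realizes the classical planted-partition benchmark — 128
nodes, four communities of 32, expected degree 16, `z_out` expected
inter-community links per node — as an independent-edge model with
$p_{in} = (16 - z_{out})/31$ and $p_{out} = z_{out}/96$. This reproduces
the stated *expected* degrees; individual degrees fluctuate binomially
(exact-degree rewired variants are deliberately out of scope). The
package's validation runs use $z_{out} = 3$, a regime where the structure
is unambiguous, and check that the search attains NMI = 1 against the
planted labels with an improving-node fraction of 0 — i.e. it returns the
planted partition *as a Nash equilibrium*. Passing these runs shows the
machinery is sound on networks with clear, equally-sized, homogeneous
communities; it says nothing about heterogeneous degree or community-size
distributions (LFR-style inputs can be read from edge-list files but are
not generated here), overlapping or weighted structure, or the hard
$z_{out} \ge 6$ regime, which needs the full published generation budgets
rather than desk-scale ones.

Partition agreement is scored by normalized mutual information with the
mean-entropy normalization
$\mathrm{NMI} = 2 I(A,B) / (H(A) + H(B))$ — the citation trail for the
usual benchmark NMI is ambiguous between normalizations, so the max-
normalization is available via `variant = "max"`; two single-community
partitions are defined to agree at 1. Confidence limits in
`improving_fraction_batch()` are normal-approximation 95% intervals, and
method comparisons (`compare_scores_ranksum()`) are delegated wholesale
to `stats::wilcox.test`.

## Validation scale

The test suite and the acceptance script run at sizes chosen to exercise
every claim without turning the suite into a compute job: exhaustive
enumeration of the subset identities on games with $n \le 6$ players and
2–3 strategies; 100-case random sweeps for oracle equivalence; five
128-node planted-partition searches at $M = 50$, 500 generations; and
the 10-firm oligopoly at 2000 generations with 5–10 replicates per $p$.
The two-clique recovery check (two 5-cliques bridged by one edge) first
confirms by brute force over all $2^9$ bipartitions that the clique split
is the modularity optimum, then requires the search to find it in at
least 9 of 10 seeded runs.

## Known limitations

* Payoff evaluation is exact rational arithmetic in floating point;
  networks large enough for $\sum d_i$ to approach $2^{53}$ would need
  care, far beyond the intended scale.
* The search is stochastic; reproducibility is per (seed, parameters),
  and solution quality at hard mixing levels depends on generation
  budgets in the thousands.
* Existence of an equilibrium of the community game is not guaranteed;
  the improving-node fraction reported by `summary()` is the honest
  certificate of how close the returned partition is.
* Directed, weighted and overlapping-community variants are out of scope.
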