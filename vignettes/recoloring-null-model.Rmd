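---
title: "The random-recoloring null model for network homophily"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The random-recoloring null model for network homophily}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recolor)
```

## The model

`recolor` treats a network with a categorical node attribute as a pair
$(G, g)$: a simple undirected graph $G$ with $n$ nodes and $m$ edges, and a
surjective coloring $g$ assigning each node one of $s$ colors. The question
"is $G$ homophilic with respect to $g$?" is answered against an *endogenous*
null model: hold $G$ fixed, and draw a coloring $F$ uniformly among all
colorings with the same profile $\mathbf c = (c_1,\dots,c_s)$ of class
sizes. There are $\binom{n}{\mathbf c}$ (multinomial) such colorings. The
model conditions on everything observable except *which* nodes carry which
color: no random-graph assumption, no degree-sequence surrogate.

Under this null, with $a^{\underline r} = a(a-1)\cdots(a-r+1)$ the falling
power, the number $M^{i,j}$ of edges whose endpoints get colors $\{i,j\}$
has exact moments

$$\bar m_{i,i} = m\,\frac{c_i^{\underline 2}}{n^{\underline 2}},\qquad
  \bar m_{i,j} = 2m\,\frac{c_i c_j}{n^{\underline 2}}\ (i\neq j),$$

$$\sigma^2_{i,i} = \bar m_{i,i}(1-\bar m_{i,i})
  + 2\left\{\left(\frac{c_i^{\underline 3}}{n^{\underline 3}}
  - \frac{c_i^{\underline 4}}{n^{\underline 4}}\right)\pi_3
  + \frac{c_i^{\underline 4}}{n^{\underline 4}}\binom{m}{2}\right\},$$

and analogously for $i \neq j$ with mixed falling-power brackets. The graph
enters only through $n$, $m$ and $\pi_3$, the number of wedges (paths on
three nodes): pairs of edges sharing a node behave differently from disjoint
pairs ($2K_2$'s, numbering $\binom{m}{2}-\pi_3$), and these two covariance
regimes are what the second-order terms capture. The z-score matrix
$\mathbf Z$ standardizes the observed counts cell by cell; diagonal cells
measure homophily, off-diagonal cells heterophily.

The companion statistic $L^i$ counts *i-isolated* nodes — nodes of color $i$
with no same-colored neighbor. Its null mean is
$\frac{c_i}{n}\sum_v (n-c_i)^{\underline{\deg v}}/(n-1)^{\underline{\deg v}}$
and its variance adds, over **ordered** non-adjacent node pairs $(u,v)$, the
factor $(n-c_i)^{\underline{b(u,v)}}/(n-2)^{\underline{b(u,v)}}$ with
$b(u,v) = |N(u)\cup N(v)|$. The ordered-pair convention (each unordered pair
counted twice) is pinned by the enumeration oracle: on the 3-path with
profile $(2,1)$ the isolated-count variance is $8/9$, which only the ordered
sum reproduces. Note the leading term $E(1-E)$ may be negative when
$E > 1$ — it is not a Bernoulli variance — while the total variance is
provably nonnegative (and asserted to be).

Finally, the number of same-colored nodes inside any fixed $t$-element set
(a node's neighborhood, say) follows the exact hypergeometric law
$\mathrm{Hyp}(n, c_i, t)$ — the binomial with falling powers substituted for
ordinary powers — exposed by `neighbor_color_pmf()`.

## Inference

The null distributions of $M^{i,j}$ and $L^i$ are not available in closed
form, so the package never pretends to know them: significance is
distribution-free. By Chebyshev's inequality the *U-value* $z^{-2}$ bounds
each cell's p-value; Cantelli's one-sided $(1+z^2)^{-1}$ is available via
`tail_bound(one_sided = TRUE)` but the two-sided bound is the default, being
the more conservative and the more conventional choice. `assess()` declares
a cell homophilic/heterophilic when $z \ge 1/\sqrt\alpha$; the procedure is
deliberately one-directional — arbitrarily negative z-scores are reported
but never "declared", so degenerate or depleted cells cannot masquerade as
findings. Cells with zero null variance (e.g. a singleton class on the
diagonal) carry `NA` z-scores and are called `undefined`, never silently 0.

For simultaneous testing, Bonferroni over $h$ cells raises the threshold to
$\sqrt{h/\alpha}$ (individual level $\alpha/h$). For the $s$ diagonal cells
this gives $\sqrt{s/\alpha}$; the literal threshold $s/\sqrt\alpha$ that is
sometimes quoted for $s$ simultaneous diagonal tests corresponds to
$h = s^2$ (all ordered cells) and is reachable through the `n_tests`
argument. Both are exposed because the two conventions genuinely differ and
neither is canonical; the default follows the family actually tested.
`q_alpha()` and `j_lambda()` give the dual descriptions of joint
significance (largest cell set whose summed U-values fit within a joint
budget $\alpha$; cells with $z > \lambda$), and
$\max\{0, 1 - s/\lVert\mathrm{diag}(\mathbf Z)\rVert^2\}$ — from the
multidimensional Chebyshev bound $\Pr\{\lVert X\rVert \ge t\} \le d/t^2$ —
is a global index in $[0,1]$ comparable across networks sharing a color set.

## Numerical design

Falling-power *ratios* like $c^{\underline r}/n^{\underline r}$ are never
evaluated as quotients of two huge products but as iterated products of
per-factor ratios $(c-k)/(n-k)$, each in $[0,1]$: stable for million-node
networks and exact zero as soon as a numerator factor crosses zero. The
variance formula is implemented twice — in closed form, and as the equivalent
sum-of-covariances decomposition — and an internal identity test keeps the
two in agreement, guarding against transcription errors in either form.

Where exactness is the point rather than speed, the package computes in
exact rational arithmetic: a small reduced-fraction class (`rat`) backs the
`exact = TRUE` paths of the moment functions, the enumeration oracle, and
the conservation identity $\sum_{i\le j}\bar m_{i,j} = m$, which holds as an
algebraic identity for every profile and is asserted exactly, not to a
tolerance. The rational class stores integer parts in doubles and aborts
beyond $2^{52}$ rather than round; at the scales where the exact paths are
used (enumeration on $n \le 7$; conservation with $n \le 80$,
$m \le 500$) this bound is far away. The exact hypergeometric pmf uses the
reduced ratio $\binom{c}{h}\binom{n-c}{t-h}/\binom{n}{t}$ and is emitted
alongside the stable floating-point path while $\binom{n}{t} < 2^{52}$.

The isolation variance has two implementations. The reference (`naive`)
loops over all ordered non-adjacent pairs with explicit neighborhood
unions, $O(n^2)$ set operations. The production path (`grouped`) rewrites
the pair sum as (all pairs, grouped by the degree histogram) minus (adjacent
pairs) minus a (distance-2 correction) using the common-neighbor table, for
$O(\sum_v \deg v^2 + D^2)$ with $D$ the number of distinct degrees; both are
exported and their agreement (to $10^{-9}$ relative on graphs up to 60
nodes) is asserted by the validation suite. In the grouped path the surrogate
exponent $\deg u + \deg v$ can exceed $n-2$; the falling-power ratio is then
an exact 0 by the numerator-first convention, which is consistent on both
sides of the telescoping correction.

## Oracles, and what the generator does and does not emulate

Two independent oracles back every closed-form moment. `enumerate_null()`
iterates the distinct colorings (multiset permutations, capped at $10^6$)
and returns exact rational moments; on *every* labeled graph with up to 5
nodes crossed with every class-size partition into at most 3 parts, plus 200
random graphs on 6–7 nodes, the closed forms match it **exactly** as
rationals — the central correctness suite. `monte_carlo_null()` recolors
uniformly (seed-controlled) and checks agreement within four standard
errors at planted-partition scale ($n$ 100–200, $10^4$ recolorings); the
standard error of the empirical variance uses the fourth-central-moment
formula, valid without normality.

`planted_partition()` generates the test fixtures: independent intra-class
edges with probability `p_in`, inter-class with `p_out`. With
`p_in == p_out` the coloring carries no signal, giving the calibration
condition under which the declaration rate at $\alpha = 0.05$ stays (far)
below 0.05 — Chebyshev's conservativeness is expected and observed. Rising
`p_in` at fixed `p_out` gives the power condition (mean diagonal z strictly
increasing along the grid 0.05–0.4 with classes of 20). The generator
emulates block structure only: real interaction networks have heavy-tailed
degrees, triangles beyond the independent-edge rate, and weighted,
noisy class assignments, none of which planted partitions reproduce — so
passing tests certify the null-model mathematics and the pipeline, not
robustness to every real-data pathology. The contrast pair
`example1_pair(p)` ($K_p + \bar K_{2p}$ against
$K_{p-1} + K_{1,p-1} + \bar K_p$, both monochromatic) shows why the
isolation statistic adds information: equal intra-class edge counts for
every $p$, but exactly twice the isolated nodes in the first graph (for
$p \ge 3$; at $p = 2$ the $K_{p-1}$ component degenerates to a lone — hence
isolated — node and the clean 2:1 ratio needs $p \ge 3$). The comparison is
made on the monochromatic graphs as constructed (3p and 3p−1 nodes); no
attempt is made to embed them in a common ambient graph with equal class
sizes, since the two verified claims (equal edge counts, 2:1 isolation) are
exact as stated.

Problem sizes used by the validation suites — exhaustive graphs to $n = 5$,
200 random graphs to $n = 7$, $10^4$ recolorings at $n = 120$–200, 500
calibration replicates at $n = 60$, 100 power replicates per grid point at
$n = 40$ — were chosen so the full suite completes in a few minutes on one
core while keeping every Monte Carlo bound at the 4-standard-error
convention.

## Input conventions

Protein-interaction inputs follow the STRING conventions: confidence
weights in $[0,999]$ with an inclusive high-confidence cutoff at 700 (the
stated "minimum weight" is read as $\ge 700$; the flag is configurable),
optional merging of isoform identifiers differing by a trailing
`_<integer>` (conflicting classes fold into the fallback class `X`, as do
classes relabelled via `merge_map`, e.g. R and S into X). Social-network
inputs follow the Pokec conventions: directed friendship lists are
symmetrized to mutual pairs only, declared ages are binned into half-open
classes C [12,18), D [18,25), E [25,40), F [40,60) with everything
missing, non-numeric or implausible in a fallback class X, and isolated
nodes are dropped after preprocessing (the builder flag `drop_isolated`
exposes the choice, since the null model itself does not require it).
Node identifiers and color labels are opaque strings; all outputs are
keyed by label, in lexicographic order, so array layouts are reproducible.

## Limitations

The U-value bounds are conservative, sometimes very much so; they are upper
bounds on p-values, not estimates. Dependence *between* cells of
$\mathbf Z$ (and between $L^i$ and $M^{i,i}$) is not modeled — the joint
statements offered are the Bonferroni-style and multidimensional-Chebyshev
ones, which remain valid under arbitrary dependence. No FDR-style
procedures are provided. The exact rational paths are bounded by the
$2^{52}$ representation guard and are meant for validation-scale inputs;
production paths are floating-point and stable at any realistic scale.
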