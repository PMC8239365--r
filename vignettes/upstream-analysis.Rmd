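---
title: "Upstream analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Upstream analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(upstreamkit)
```

This vignette is the package's own account of the science it implements:
what each stage assumes, which tunables matter and why their defaults are
what they are, what the synthetic-data generator does and does not emulate,
and where the design was genuinely open.

## The problem

In a two-group expression study (the motivating setting is aggressive vs
indolent tumors, e.g. glioblastoma short- vs long-term survivors), lists of
differentially expressed genes describe *what* changed but not *why*.
Upstream analysis works backwards from the dysregulated genes in two moves:
first it asks which transcription factors plausibly drive them, by looking
for TF binding-site patterns that distinguish the promoters of upregulated
("yes") genes from background ("no") promoters; then it asks which
signaling molecules sit upstream of those TFs in a directed signaling
network, with special interest in molecules whose own genes are targets of
the same TFs — positive feedback loops that can lock a pathological
expression program in place.

## Stage 1: moderated differential expression

The model is the standard hierarchical one for gene-wise variances: for
gene $g$ with pooled two-group variance $s_g^2$ on $d_g = n_1 + n_2 - 2$
degrees of freedom, a scaled inverse-chi-square prior
$s_0^2$, $d_0$ shrinks each variance to
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$; the moderated t uses
$\tilde s_g$ and $d_0 + d_g$ df. The prior is fit by method of moments on
$\log s_g^2$: $\mathrm{var}(\log s_g^2) = \psi'(d_g/2) + \psi'(d_0/2)$,
inverted for $d_0$ with Newton steps on the trigamma function. When the
moment equation has no root (observed spread of log-variances below the
pure chi-square floor), $d_0$ falls back to 4 — this only occurs in
near-degenerate fixtures. The test suite checks the two analytic limits
($d_0 = 0$: ordinary per-gene t; $d_0 = \infty$: pooled common variance)
and agreement with an independent implementation of the moderated t on
simulated data.

Direction calls use adjusted $p < \alpha$ and $|\log_2 FC| > \tau$ with
defaults $\alpha = 0.05$, $\tau = 0.5$ (log2 units). The sign convention is
YES minus NO, stated in every output header.

**The "no" promoter set** is a genuine design decision: the contrast wants
promoters of genes *unchanged* under the same conditions. The default is
non-significant genes with $|\log_2 FC| < 0.1$ (an expression-matched
background), capped at 10x the yes-set size by seeded subsampling. Both
thresholds are exposed (`ns_lfc`, `cap_ratio`).

## Stage 2: MATCH-style scanning

A motif is a position frequency matrix, normalized per position, then
regularized with pseudocount $\varepsilon = 0.001$ *after* normalization
(so scoring is invariant to rescaling counts) and renormalized. The
information vector $I(i) = \sum_b f(i,b)\ln 4f(i,b)$ weights each
position; the matrix similarity of a window $s$ is

$$\mathrm{MSS} = \frac{\sum_i I(i) f(i, s_i) - \sum_i I(i)\min_b f(i,b)}
                      {\sum_i I(i)\max_b f(i,b) - \sum_i I(i)\min_b f(i,b)}
  \in [0, 1],$$

and the core similarity CSS is the same quantity restricted to the 5
consecutive positions of maximal summed information (leftmost on ties;
a motif shorter than 5 positions uses all of them). Both strands are
scanned — the reverse strand by scoring the forward sequence against the
reverse-complemented matrix — and reverse hits are reported in forward
coordinates (the 5'-most matched base). Windows overlapping an `N` are
skipped and excluded from the scannable-position counts that the
enrichment null uses.

Coordinates are TSS-relative, 0-based, half-open $[start, end)$ with the
TSS at 0, so the default window $[-1000, +100)$ has length 1100. Default
cutoffs are MSS ≥ 0.75 and CSS ≥ 0.70: deliberately permissive, because the
module stage re-thresholds per motif anyway, and overridable globally or
per motif. Overlapping hits of the same motif are all retained.

## Stage 3: yes/no enrichment

For motif $m$ with $k$ occurrences in yes promoters out of $n$ total, the
null allocates occurrences proportionally to scannable length,
$p_0 = L_{yes}/(L_{yes}+L_{no})$, and the p-value is the exact tail
$P[\mathrm{Bin}(n, p_0) \ge k]$ by direct summation (cross-checked against
the regularized incomplete beta to 1e-10). A per-promoter-count null
(`null_model = "promoter"`) is provided as the alternative; the
length-proportional null is the default because the statistic counts
occurrences, not presence. The reported ratio is Haldane–Anscombe
pseudocounted, $((k+\tfrac12)/n_{yes}) / ((occ_{no}+\tfrac12)/n_{no})$, so
it is finite for empty counts (and equals $n_{no}/n_{yes}$, not exactly 1,
when both counts are zero and the sets differ in size). BH adjustment runs
across motifs; candidate TFs pass adjusted $p < 0.05$ and ratio > 1,
ordered by raw p with ties broken by larger ratio then motif id.

## Stage 4: composite modules

A composite module is $2..k_{max}$ motifs, each with threshold
$\theta_m \in \{0.70, 0.75, \dots, 0.95\}$ and positive weight $w_m$
(normalized to sum 1), plus a window width
$W \in \{100, 150, \dots, 600\}$ bp. A promoter's module score is the best
window placement,
$\max_s \sum_m w_m \max(0, \mathrm{best\ MSS}_m[s, s+W) - \theta_m)$,
computed exactly: the optimum is always attained anchoring the window at a
hit start, and a monotone-deque sweep makes scoring linear in the
promoter's hits (the C++ scorer is tested against brute-force enumeration
of every integer window start).

No published objective exists for this kind of module search, so fitness is
the simplest defensible discrimination statistic: Welch t of yes vs no
module scores minus a complexity penalty $\lambda k$ ($\lambda = 0.1$;
variances floored at 1e-12 for degenerate separations). A tie-corrected
Mann–Whitney z is provided as a pluggable alternative (`objective =
"wilcoxon"`).

The genetic algorithm uses chromosomes of $k_{max}$ motif slots (empty
slots allowed, at least 2 filled, no duplicate motifs), tournament
selection of size 3, uniform crossover on slots, and four mutation moves:
motif swap/toggle, $\theta$ jitter of one grid step, weight jitter by
$U(0.8, 1.25)$, window jitter of one grid step. Elitism keeps the best
chromosome, so the fitness trace is non-decreasing; all randomness flows
from one seed, so a fixed seed is bit-reproducible. A hall of fame of the
best chromosome per distinct motif set supplies the requested number of
motif-disjoint modules (fewer, with a warning, when the pool is too small
to fill them — a 3-motif pool cannot yield two disjoint modules). On
two-motif instances the GA is tested against exhaustive search over the
threshold and window grids.

**Permutation significance.** The observed fitness is *refit* — one
deterministic coordinate-ascent pass over the $\theta$ grid, the $W$ grid
and per-motif weight scalings, with the motif set fixed — and compared with
the same refit under label permutations:
$p = (1 + \#\{f_{perm} \ge f_{obs}\})/(n_{perm}+1)$ with
$n_{perm} = 199$ by default (at least 19 enforced). Refitting observed and
permuted labels with the identical procedure makes the p-value exchangeable
under the null; its uniformity is verified by a KS test over repeated
label-shuffled datasets.

The per-gene **regulatory score** is the maximum over fitted modules of the
gene's module score; the two modules' scores are summed only for the
combined reporting column.

## Stage 5: master regulators

Candidates are network nodes from which at least `m_min = 2` module TFs are
reachable through directed SIGNALING edges within radius `r = 4` (module
TFs themselves are excluded — the search is for upstream signaling
molecules, not for TF cross-regulation). The network score is
distance-discounted coverage,

$$\mathrm{mr\_score} = \frac{1}{|T|} \sum_{t \in reached}
   \frac{r - d(c,t) + 1}{r} \in (0, 1],$$

so a node at distance 1 from every TF scores exactly 1 (star graph) and a
chain $c \to a \to t$ at $r = 2$ scores 0.5. The score is a package
construction — only its intent (closeness to many module TFs) is inherited
from the field — and is pluggable; plain coverage $|reached|/|T|$ is the
alternative. Distances are verified against an independent Floyd–Warshall
implementation.

A **feedback loop** is recorded for candidate $c$ and reached TF $t$ when
the circuit closes transcriptionally: a TRANSCRIPTION edge from $t$ onto a
node carrying $c$'s encoding gene (`NETWORK_EDGE` evidence), or a
module-passing site for $t$'s motif (MSS above that motif's module
threshold) in the gene's promoter (`PROMOTER_SITE` evidence). Loops are
labeled positive when the product of signaling-edge signs along the
shortest path is +1; negative-product loops are kept but flagged, since
sign-definite loop semantics are otherwise underdetermined.

Ranking averages three component ranks — encoding-gene log2FC, regulatory
score, network score, each descending. Ties within a component take
midranks (`ties.method = "average"`): minimum-ranks would let several tied
candidates all claim rank 1 and jointly displace a candidate that wins the
other two components, which is a ranking artifact rather than evidence.
Final ties break lexicographically by node id. Candidates without an
encoding gene take log2FC = 0 and regulatory score = 0. The output reports
both TF-support counts (network-reachable TFs, and TFs with
promoter-site support), since either reading of "number of TFs regulated"
is defensible.

## The synthetic-study generator

`gen_study(seed)` emulates the statistical skeleton of a two-group cohort
study with planted ground truth; each artifact draws from an independent
seed stream, so regenerating one leaves the others bit-identical.

* **Expression**: 2000 genes x (20 + 20) samples; baselines $N(7, 1)$;
  150 up / 100 down planted genes with effects $U(0.6, 1.5)$ log2 units;
  Gaussian noise $\sigma = 0.5$. These sizes put the planted effects near
  the detection boundary of the DE thresholds (an effect of 0.6 is ~3.8
  noise SEs), which is what makes recall a meaningful measure.
* **Motifs**: 20 Dirichlet-sampled PFMs of length 8–14, tempered to a mean
  information content of 1.2 ± 0.2 bits/position.
* **Promoters**: 50 yes + 200 no promoters of 1100 bp (window
  $[-1000, 100)$), background GC 0.5. Yes promoters carry, with
  probability $\pi = 0.9$, one site per module motif placed
  non-overlapping inside a random 300 bp window; no promoters carry
  Poisson(0.5) decoy singletons. Planted sites are sampled from the PFM
  *conditioned on MSS ≥ 0.9* (rejection sampling): this models strong
  functional sites and guarantees a scanner at cutoff 0.9 rediscovers
  every recorded implant.
* **Module choice**: the planted module defaults to the 3 *most
  informative* library motifs. This is deliberate: at the default scanning
  stringency, an 8-mer at 1.2 bits/position has a background hit rate near
  1% per offset, so its occurrence counts are dominated by background and a
  single planted site per promoter is statistically invisible — whereas
  14-mers sit near $10^{-3}$–$10^{-4}$ and give the planted module a
  clearly detectable enrichment signal. Real composite-module TFs are
  likewise the specific, information-rich binders.
* **Network**: 300 background nodes with mean out-degree 2.5 (background
  edges stay among background nodes), the planted regulator wired to every
  module TF by activating paths of length ≤ 3, distractor hubs reaching at
  most $\lceil|T|/2\rceil$ TFs, and TRANSCRIPTION feedback edges from
  every module TF onto the regulator node, whose encoding gene is the
  planted up-gene with the largest effect and always carries the module
  cluster in its promoter. This encodes the positive-feedback premise as
  generative structure, so end-to-end recovery exercises the whole chain.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: probe-level microarray noise, batch effects,
correlated genes, GC-content or CpG-island structure in promoters,
dinucleotide background, motif similarity/redundancy within the library,
and the literature bias of curated signaling networks. The planted-truth
results certify the machinery, not performance on any particular cohort.

## Numerical choices and degenerate inputs

Exact binomial tails by term summation (cross-checked to 1e-10 against the
incomplete beta); BH through the standard step-up routine behind a
validating wrapper; p-values floored away from 0 only by the double
minimum; Welch variances floored at 1e-12; zero-variance genes handled by
shrinkage, never division by zero; motifs shorter than 5 positions use the
whole matrix as core; promoters shorter than a motif scan to an empty hit
list; an empty up-regulated set short-circuits the pipeline into a
structured "no DEGs" report. All tie-breaks (enrichment ordering, GA
hall-of-fame, ranking) are total and documented, which is what makes
fixed-seed reruns byte-identical.

## Problem sizes used by the test suite

The acceptance tests run the generator at its default study conditions for
seeds 1–20 (calibration and recovery), two-motif GA-vs-exhaustive
instances at 12 + 24 promoters of 600 bp, permutation-null calibration at
10 + 20 promoters of 400 bp with 39 permutations x 200 replicates, and
graph oracles on networks of ≤ 50 nodes; the whole suite completes in a
few minutes on one CPU. `scripts/acceptance.R` reports means over 5
studies per run.

## Known limitations

The enrichment null ignores sequence composition (no CpG matching); the
module objective treats promoters as exchangeable units (no pairwise
distance or orientation constraints between sites); the GA's threshold
grid bounds resolution at 0.05; master-regulator search does not use edge
signs for reachability (only for loop labeling); and the three-component
rank average weights its components equally, which is a convention, not an
inference.
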