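---
title: "Methods: miRNA synergy networks and association statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA synergy networks and association statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcmirnet)
```

## The analysis this package implements

Colorectal tumours dysregulate microRNAs, and dysregulated miRNAs rarely act
alone: two miRNAs whose target genes converge on the same pathways behave as
a functional unit. `crcmirnet` implements the computational arm of that style
of study end to end:

1. **Paired differential calling.** Each patient contributes matched
   normal/adenoma/carcinoma tissue, so deregulation is assessed by a paired
   two-sided t-test on log2 expression differences, combined with a
   fold-change filter.
2. **Per-miRNA pathway enrichment.** Each deregulated miRNA's verified
   target set is tested against a pathway database with the right-sided
   hypergeometric test, corrected by the Holm (Bonferroni step-down)
   procedure, and redundant enriched terms are grouped by Cohen's kappa over
   gene membership.
3. **Synergy networks.** miRNA pairs are joined by edges when they
   co-regulate enriched pathways, share upstream transcription factors, or
   are strongly co-expressed; the hub score of a node is its weighted
   degree.
4. **2x2 association.** Joint marker-positivity counts are summarised by the
   odds ratio with a Woolf (log-normal) confidence interval and an exact or
   chi-square test.
5. **Synthetic data.** A generator reproduces the statistical structure all
   of the above assumes, so the full pipeline is testable with no external
   downloads.

## The differential model

For miRNA $m$ with paired log2 values $x^{(b)}_{mp}, x^{(a)}_{mp}$ in the two
classes, the statistic is the one-sample t-test on
$d_{mp} = x^{(b)}_{mp} - x^{(a)}_{mp}$, and
$\log_2\mathrm{FC}_m = \bar d_m$ (the mean of paired differences, not the
log of a ratio of means — a declared convention). The default decision rule
is raw $p < 0.05$ **and** $|\log_2\mathrm{FC}| \ge 1$; array studies of this
design typically report "t-test, P < 0.05" without a multiplicity
correction, so `adjust = "none"` is the default, with Holm and
Benjamini-Hochberg available. Degenerate rows are resolved explicitly: zero
within-pair variance gives $p = 0$ when $\bar d \ne 0$ and $p = 1$
otherwise (flagged), and rows with missing paired values are never called.

## Enrichment conventions

The right-tail probability $P(X \ge k)$ for
$X \sim \mathrm{Hypergeometric}(N, K, n)$ is accumulated from `lchoose`
terms in log space, so pathway databases of any size are safe from
overflow; on every instance with $N \le 40$ the result agrees with exact
rational enumeration to better than ten significant digits (the test suite
sweeps all of them).

Three conventions are deliberate design choices, because the analysis style
leaves them open:

* **The multiple-testing family is the set of pathways tested for one
  miRNA**, not the global miRNA-by-pathway grid. Enrichment is run per
  target list, so each list is its own family.
* **The gene universe defaults to the union of all pathway genes** and is
  overridable. Target genes outside the universe are discarded before
  testing.
* **Kappa grouping is single-linkage**: enriched terms are vertices, pairs
  with kappa $\ge 0.3$ (default) are edges, and connected components are the
  groups. Each group is represented by its lowest adjusted-p member, ties
  broken lexicographically. Kappa is Cohen's chance-corrected agreement of
  the two membership indicators over the universe; identical indicators
  (including two empty sets) score 1 by definition.

## Network conventions

An edge in the pathway-synergy network requires at least one **shared
enriched pathway** — the reading in which edges represent co-regulated
pathways; the count of shared enriched pathways is the weight, and the ids
are kept as edge evidence. For users who prefer the raw-annotation reading
(shared verified target genes), `target_synergy_network()` builds that
variant. TF-synergy edges count shared upstream regulators. Correlation
edges require $|r| \ge 0.7$ (Pearson by default, Spearman optional) within
one tissue class; the threshold, method and class are exposed because the
design leaves them open, and the signed coefficient is retained per edge so
inverse co-expression stays visible.

"Node size" — what makes a hub look large in a synergy-network figure — is
operationalised as **weighted degree**: the sum of incident edge weights.
That is the minimal quantitative interpretation of node prominence, and it
satisfies the handshake identity (total hub score equals twice the total
edge weight), which the tests assert on every build.

Networks are deterministic functions of their inputs: endpoints are stored
lexicographically, rows sorted, so repeated builds serialize byte-identically.

## Association conventions

The odds ratio of a 2x2 positivity table is $(ad)/(bc)$, with the
Haldane–Anscombe $+0.5$ correction applied to all cells **only** when a zero
cell is present (and recorded in the result's `method` field). The interval
is Woolf's log-normal interval,
$\exp(\log \mathrm{OR} \pm z_{0.975}\sqrt{1/a + 1/b + 1/c + 1/d})$, chosen
because it reproduces the printed intervals of the packaged positivity
fixture from the printed counts. The significance test is user-selectable
(Fisher exact by default, chi-square with or without Yates correction),
since positivity tables in the literature often do not name their test.

## What the generator emulates — and what it does not

`simulation_config()` defaults describe the study conditions the pipeline is
validated against: an 830-miRNA array over six patients with all three
tissue classes, 40 planted up- and 8 planted down-regulated miRNAs at
$|\log_2\mathrm{FC}| = 1.5$, per-observation Gaussian noise of sd 0.3 on the
log2 scale, and a sign-switching co-expression module linking miR-155 to
miR-143/145/192/378.

Design choices, with reasons:

* **Expression is generated directly on the log2 scale** with per-miRNA
  baselines uniform on $[4, 12]$. Array studies of this kind report only
  relative expression, so an intensity-level model would add arbitrary
  structure the analysis never uses.
* **Adenomas receive 50% of the carcinoma effect** (configurable). The
  intermediate lesion is described as initially deregulated; absent a stated
  magnitude, half-effect is a declared convention, not an inference.
* **The sign-switching correlation uses realised loadings.** The hub
  miRNA's residual is a latent factor whose loading flips sign in normal
  tissue; each group member mixes the factor (loading `corr_strength`) with
  its own noise. With only six samples per class, a *population*
  correlation of 0.8 would be realised so noisily that the inverse
  relationship would frequently be invisible in any single simulated study —
  the opposite of what the generator is meant to emulate. The factor is
  therefore standardised within each class and the member noise
  orthogonalised against it in-sample, making the within-class sample
  correlation exactly $\pm$`corr_strength`. Every miRNA keeps identical
  residual variance, so the correlation module does not distort the power
  of the paired test; a side effect is that the hub and group miRNAs
  recover their planted fold changes exactly. Below three pairs per class
  the standardisation is undefined and the raw mixture is used.
* **One global seed derives per-component child seeds** (a string-hash of
  the component name folded with the seed), so adding a generator component
  never perturbs the draws of existing ones, and equal seeds give
  bit-identical output.
* **The annotation bundle is engineered, not neutral.** Every planted
  miRNA's target set heavily samples (70%) the genes of two "signal"
  pathways, and each non-hub miRNA draws its first signal pathway from the
  hub's six — guaranteeing that the hub shares an enriched pathway with
  every planted partner and therefore tops the hub ranking, the structure
  the network stage is validated against. The TF map always carries the
  literature-anchored edges SMAD3/SMAD4 → miR-155 and CEBPB → miR-143.
  An infeasible constraint (gene pool smaller than the largest requested
  pathway) is an error, never silently relaxed.

The generator does **not** emulate probe-level intensities, normalization
artifacts, batch effects, or missingness; passing tests therefore say
nothing about robustness to those features of real array data. Sample
metadata, annotation formats and GMT files are exactly as strict as the
readers: validation failures reject the input rather than repairing it.

## Numerical choices and degenerate inputs

* Hypergeometric tails: log-space summation with a max-shift
  (log-sum-exp); $k = 0$ returns exactly 1; results clamped to $[0, 1]$.
* Holm: stable ascending sort, cumulative maximum of
  $(m - j + 1)\,p_{(j)}$, capped at 1; `NA` p-values pass through without
  counting toward $m$.
* Kappa: $p_e = 1$ implies identical indicators and returns 1, avoiding
  0/0.
* Correlation networks drop zero-variance miRNAs with a warning (their
  Pearson r is undefined) and refuse classes with fewer than three samples.
* Contingency tables reject non-integer or all-zero cells; percentages are
  reported to two decimals, the precision positivity tables print.
* All file writers emit doubles as `%.17g`, so write→read round trips are
  bit-exact.

## Problem sizes used by the test suite

The suite validates the default 830-miRNA, six-pair profile directly (it
runs in well under a second per simulation). Brute-force network oracles
run on fixtures of up to 50 miRNAs; the exhaustive hypergeometric sweep
covers every valid $(k, K, n, N)$ with $N \le 40$; the positivity
simulator's odds-ratio calibration uses 4,000 Monte-Carlo replicates at
$n = 78$. These sizes were chosen to exercise every code path with exact or
near-exact oracles while keeping the suite fast enough to run on every
change.

## Known limitations

* The pathway-synergy definition requires *enriched* shared pathways; two
  miRNAs sharing many targets that never reach enrichment will not be
  joined (use `target_synergy_network()` for that reading).
* The paired t-test assumes approximate normality of paired differences on
  the log2 scale; no moderated-variance (empirical Bayes) alternative is
  provided.
* Enrichment treats pathways as flat gene sets: no ontology hierarchy, no
  term pruning.
* The association module is limited to single 2x2 tables — no stratified
  (Mantel–Haenszel) or regression adjustment.

## A minimal worked run

```{r example, eval = FALSE}
cfg <- simulation_config(seed = 42)
expr <- simulate_expression(cfg)
diff <- differential_mirnas(expr, "normal", "carcinoma")
table(diff$call)

ann <- simulate_annotations(cfg)
de <- diff$mirna[diff$call != "ns"]
enr <- enrich_mirna_targets(ann$target_map[intersect(de, names(ann$target_map))],
                            ann$pathway_db)
head(hub_ranking(pathway_synergy_network(enr)))

associate_2x2(contingency_2x2(28, 21, 9, 20))
```
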