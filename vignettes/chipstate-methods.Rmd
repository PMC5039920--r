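---
title: "Methods: the discretization model, its estimation, and the quality-control classifier"
author: "chipstate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the discretization model, its estimation, and the quality-control classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipstate)
```

## The emission model

Counting reads per fixed-step genomic window produces data that a
Poisson model fits poorly: windows differ in copy number, mappability
and PCR propensity, so the variance exceeds the mean. A negative
binomial absorbs that overdispersion, but still underestimates the
number of empty windows, because repeat-rich regions can never
receive a uniquely mapped read. The univariate emission model is
therefore the zero-inflated negative binomial (ZINB): a point mass at
zero with weight $\pi$ (the fraction of unmappable windows) mixed
with a negative binomial with shape $\alpha$ and success probability
$p$.

With $r$ replicates the counts of a window are correlated, because
the window-level biases are shared by every experiment performed on
the same material. The natural multivariate extension runs through
the Gamma–Poisson construction of the negative binomial: draw one
Gamma($\alpha$, 1) intensity $G$ per window, then per-replicate
Poisson counts with rates $G\lambda_j$. Marginalizing $G$ yields the
negative multinomial with probabilities
$p_0 = 1/(1+\sum_j\lambda_j)$ and $p_j = \lambda_j p_0$, and adding
the unmappable class gives the zero-inflated negative multinomial
(ZINM)

$$
g(y\mid\theta)=
\begin{cases}
\pi+(1-\pi)p_0^{\alpha} & y = 0,\\[2pt]
(1-\pi)\dfrac{\Gamma(\alpha+y_1+\cdots+y_r)}
{\Gamma(\alpha)\,y_1!\cdots y_r!}\,
p_0^{\alpha}p_1^{y_1}\cdots p_r^{y_r} & \text{otherwise,}
\end{cases}
$$

with $p_0+p_1+\cdots+p_r=1$. The expected count of replicate $j$ is
$\alpha\,p_j/p_0$. Biases are thus modeled implicitly, through the
variance and correlation structure, not from sequence features such
as G+C content — a deliberate simplification that keeps the model
applicable to any genome without annotation.

All probability mass computations run in log space through
`lgamma()`; no factorial is ever formed. `dzinb()` and `dzinm()` are
verified to sum to one on truncated supports (tolerances $10^{-9}$
univariate, $10^{-6}$ bivariate) and the $r=1$ multivariate case
reduces exactly to the univariate one.

## Why three states

Many profiles show piece-wise baseline variation of low amplitude but
10–100 kb extent. A two-state segmentation frequently locks onto
those blocks instead of the targets. Dedicating two states (low and
medium) to the baseline leaves the third free to capture the targets;
the 'high' state windows are the reported targets, always. The number
of states is fixed at three; it is not a tuning knob.

## Estimation

**Baseline first.** $\pi$ and $\alpha$ describe window behaviour, not
feature abundance, so they are estimated once from the negative
controls (summed per window when there are several, which is exact
under the shared-intensity model) and pinned for the rest of the
procedure. Estimating them inside the EM loop would let the
zero-inflation drift toward whatever the current segmentation finds
convenient; pinning them avoids that instability.

`fit_zinb()` maximizes the ZINB likelihood with a short
expectation–maximization warm start over the latent unmappable-window
indicator, followed by a damped Newton–Raphson ascent on the full
score with the analytic Hessian. The M-step's shape update solves the
profile score equation in $\alpha$ (with the odds parameter profiled
out at $p_0=\alpha/(\alpha+\mu)$) by Newton iteration safeguarded by
a sign-change bracket and bisection fallback. Initial values are
method-of-moments, with $\pi$ started at the excess-zero fraction
relative to the moment negative binomial and floored at zero.
Boundary fits ($\pi=0$) are valid outputs — Poisson-like data should
and do collapse to an uninflated fit, with $\alpha$ escaping to its
upper cap in the quasi-Poisson regime. Convergence is declared at a
relative log-likelihood change below $10^{-8}$ or a score sup-norm
below $10^{-6}$ per observation, within 200 iterations; the damped
Newton stage typically needs fewer than ten and lands within
$10^{-10}$ log-likelihood units of an independently run
quasi-Newton optimizer.

**Baum–Welch.** The E-step runs scaled (per-position normalized)
forward–backward recursions; scaling was preferred over log-space
recursions because it is standard, fast, and exactly testable against
both a log-space enumeration oracle and brute-force path summation at
small $n$. Chromosomes are independent chains restarted from $\nu$
with their log-likelihoods summed — the model is silent on what a
transition across a chromosome junction would mean, and independence
avoids inventing one. The M-step re-estimates $\nu$ from the chain
starts, the transition matrix $Q$ from expected transition counts,
and each state's probability vector by maximizing the
responsibility-weighted ZINM likelihood: given $p_0$ the replicate
probabilities are proportional to weighted column sums, so the update
reduces to one-dimensional bracketed Newton root-finding on the
profile score of $p_0$. A state whose total responsibility falls
below $10^{-8}$ keeps its emission parameters for that iteration and
a warning is raised. Default controls: relative tolerance $10^{-6}$,
at most 100 iterations. The log-likelihood trace is checked to be
non-decreasing (slack $10^{-6}$ relative) in the test suite across
dozens of seeded datasets.

**Initialization** is deterministic, so a run is reproducible without
any seed: windows are split by total chip count into the bottom 50%,
next 40% and top 10% to seed the three emission states, $\nu$ starts
uniform and $Q$ sticky (0.95 diagonal). The split mirrors the
expectation that targets are a minority of the genome. Label
switching at initialization does not affect results: roles are
assigned after fitting, by ranking states on their implied expected
total chip signal $\alpha\sum_j p_j/p_0$ (ascending → low, medium,
high). Exact ties — which occur for genuinely enrichment-free data —
fall back to raw state order with a warning.

**Decoding.** The reported track is the Viterbi path, decoded per
chromosome; posterior decoding is available through the returned
posteriors but is not the caller. Ties in the maximization are broken
toward the lower state index at every step, which makes the decoder
deterministic; the property is pinned by a symmetric-construction
test. The per-window confidence is the posterior probability of the
Viterbi state. Windows that are zero in every profile stay in the
chain (the zero-inflation term absorbs them) but are excluded from
reported targets: a window where no read can map should never be
called a binding site, even when its neighbours are.

**Parameter accounting.** The conventional size of the model is
$3r+9$ free parameters for $r$ replicates: the $3\times(r+1)$ table
of state-dependent emission probabilities plus the six free entries
of the row-stochastic transition matrix, with the baseline pair
$(\pi,\alpha)$ counted as pre-fitted and the initial distribution
with the transition structure. A strict simplex accounting instead
counts $r$ free probabilities per state, 6 in $Q$, 2 in $\nu$ and the
baseline pair, for $3r+10$ independently estimated scalars across the
whole procedure. `n_free_parameters()` returns the conventional total
and attaches the strict breakdown as an attribute.

## Quality control

Five statistics summarize a discretization (`qc_features()`):

| feature | meaning | degenerate value |
|---|---|---|
| `q_high_to_low` | $Q$[high, low]; how abruptly targets end (peak size proxy) | — |
| `min_snr` | $\min_j$ rate$_j$(high)/rate$_j$(medium) | $\approx 1$ without enrichment |
| `target_fraction` | share of windows called high | $\approx 0$ without enrichment |
| `var_explained` | between-state / total sum of squares of mean chip count | 0 when states are interchangeable |
| `replicate_correlation` | mean pairwise Pearson correlation of replicate columns | low for non-replicates |

Two readings of the phrase behind `var_explained` were possible
(per replicate then averaged, or on pooled counts); the one-way
between/total sum-of-squares ratio on the per-window mean chip count
is implemented as the simplest construction matching the phrase, and
the same decomposition is exposed as `variance_explained()` for
benchmarking against external responses. `replicate_correlation`
uses untransformed window counts, again the simplest reading; both
choices are isolated behind the feature interface and easy to swap.
The signal-to-noise ratios are per-replicate high/medium emission
mean ratios; with a single replicate the correlation feature is a
sentinel 1.0 with a warning (quality control is only meaningful from
two replicates up). In the emission-rate ratio notation, index runs
over ChIP replicates: the control profile does not enter the
emission vector here — it acts only through the pinned baseline pair.

The classifier is a radial-basis-function SVM: it handles the
visibly nonlinear class boundary in this five-dimensional space and
has exactly two hyperparameters (cost and kernel width), which are
selected by stratified 10-fold cross-validation over a small grid on
standardized features, then refit on the full corpus.

A curated corpus of labeled experimental discretizations is not
shippable inside a source package, and labels on real data are partly
subjective in any case. The package therefore ships the training
*pipeline* plus a simulator-generated surrogate corpus
(`build_training_corpus()`): positives are simulated replicated
experiments with true enrichment under randomized depths
(×0.5–2), shapes ($\alpha \in [2,6]$), unmappable fractions
(0.05–0.20) and state separations; negatives split evenly between
(a) enrichment-free profiles treated as ChIP — the no-antibody
failure mode — and (b) pairs of profiles with independent target
sets treated as replicates — the sample-swap failure mode.
`default_qc_model()` trains this model on demand and
deterministically; a model trained on curated real data can be
supplied wherever a `qc_model` is accepted. Cross-validated accuracy
on the synthetic corpus exceeds 0.90 (shuffled labels sit at
chance). That figure shows the features separate the simulated
failure modes; it is *not* evidence about accuracy on experimental
data, whose failure modes are richer than the two simulated ones.
The verdict is all-or-none for the profile: a dataset whose
replicates disagree is better rejected whole than silently reduced
to its common peaks.

## The simulator

`simulate_chip()` realizes exactly the generative model above:
per-chromosome Markov chains, joint window-level unmappability (an
unmappable window is zero in *every* profile, controls included),
one shared Gamma intensity per mappable window, Poisson counts per
profile, controls drawn at a state-independent baseline rate.
Defaults — two chromosomes × 5000 windows of 300 bp, two replicates,
$\pi=0.10$, $\alpha=4$, control mean 4 reads/window, state means
2/8/32 reads/window, sticky transitions with ~9% stationary mass in
the high state — describe a moderately deep experiment with
well-separated states, the regime in which recovery guarantees are
stated: on 50,000 windows the baseline pair comes back within 5%
relative, transition entries within 0.05 absolute, and ≥95% of
windows receive their generating state. `emit_bed()` writes the
counts back out as distinct-position 36 bp reads so that the full
file pipeline (parsing, deduplication, midpoint binning) round-trips
to the truth matrix exactly, with optional injected duplicates to
exercise deduplication.

What the simulator does *not* emulate: fragment-length and sonication
effects, G+C and mappability structure along the genome (biases are
exchangeable across windows here), copy-number segments, batch
effects, or broad-domain/sharp-peak shape differences beyond what the
transition matrix expresses. Tests passing on simulated data
therefore validate the estimation machinery and the failure-mode
geometry of the QC features, not performance on any particular
experimental profile.

## Preprocessing choices

Coordinates are 0-based half-open internally; BED is consumed as-is,
SAM/BAM (1-based inclusive) converted on read. Unmapped, secondary
and supplementary alignments are skipped. PCR duplicates are
collapsed to the first read per (chromosome, 5′ position, strand) —
the 5′ end is invariant to 3′ soft-clipping differences, which makes
it the stable notion of "same location". Read midpoints are
$\lfloor(start+end)/2\rfloor$, integer-only and deterministic for
even-length reads. Reads on chromosomes absent from the grid are
skipped with a summary warning rather than an error, to tolerate
decoy contigs; a midpoint beyond the declared chromosome length goes
to the last window with a warning. A profile averaging fewer than 3
reads per window triggers a window-size warning, since the window
should be wide enough to hold 3–4 reads on average and no narrower
than the sonication fragment. GEM-format input is not supported
(BED/SAM/BAM only); paired-end mates are treated as two reads.

## Discretizer comparison utilities

Ordering windows by decreasing count and accumulating yields the
Pareto front: the maximum number of reads capturable by $k$ target
windows, for every $k$. Any discretization is a point (number of
targets, reads captured) on or below that curve, which gives a
partial order on discretizers without requiring a gold standard.
`motif_benchmark()` scores peak sets against a motif reference with
≥1 bp overlap semantics on half-open intervals (precision = peaks
with a motif / peaks; recall = motifs covered / motifs; F1 their
harmonic mean, defined as 0 when both vanish); optional resizing of
peaks to a fixed width around their center is available but off by
default. `variance_explained()` takes pre-joined (response, group)
pairs; mapping windows to genes is out of scope.

## Problem sizes and determinism

The test suite and the acceptance script size their simulations to
run comfortably on one CPU: exhaustive-enumeration oracles at
$n \le 8$ windows, solver comparisons on 20 datasets of 2000 counts,
recovery on 50,000 windows, the QC corpus at 200 cases per class of
1500 windows each. Every stochastic step is seeded; the EM itself has
no randomness (deterministic initialization), so a discretization of
fixed inputs is bit-reproducible.

## Known limitations

The state count is fixed at three; profiles whose baseline needs more
structure will fold it into the medium state. $\pi$ and $\alpha$ come
from the controls, so a missing or unrepresentative control degrades
everything downstream — the model implicitly assumes the user's
controls capture the systematic biases of the ChIP experiments. The
QC classifier shipped by the package knows only simulated failure
modes. No per-peak p-values or FDR are produced: the output is a
segmentation with per-window posterior confidences, not a ranked
peak list.
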