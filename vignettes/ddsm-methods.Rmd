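---
title: "Substitution-matrix-aware motif encoding: model and design notes"
author: "ddsm package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Substitution-matrix-aware motif encoding: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddsm)
```

## The problem

Sequence classifiers need fixed-width numeric inputs. The common route is
to mine motifs (substrings) from a labeled protein corpus, use each motif
as a binary attribute, and encode every sequence as the 0/1 vector of
motif presence — the *learning context*. Plain discriminative-descriptor
(DD) mining treats motifs as opaque strings, which ignores a basic fact of
protein chemistry: many amino-acid replacements are near-neutral, so a
family's signature motif appears across its members in slightly mutated
forms. Treating each mutated form as a separate attribute inflates the
feature space and scatters the signal; marking a sequence 0 for a motif
whose near-equivalent it actually contains discards information.

The DDSM encoding implemented here fixes both problems with an amino-acid
substitution matrix (BLOSUM/PAM): motifs that are mutually substitutable
collapse to a single representative feature, and presence marking accepts
substitutes.

## The motif calculus

All quantities derive from a 20x20 symmetric integer substitution matrix
with entries $S(x, y)$.

**Residue conservation.** For residue $x$,
$$P(x) = \frac{S(x,x)}{\sum_{y:\,S(x,y) > 0} S(x,y)},$$
the diagonal score normalised by all strictly positive scores in $x$'s
row. $P(x) = 1$ exactly when no other residue scores positively against
$x$; under BLOSUM62 that holds for C, G and P only (a brute-force row scan
in the test suite verifies the set).

**Motif mutation probability.** For a motif $M$ of length $k$,
$$P_m(M) = 1 - \prod_{i=1}^{k} P(M[i]) \in [0, 1),$$
the probability that at least one position mutates. A motif of fully
conserved residues (e.g. GGP) has $P_m = 0$.

**Substitution score and probability.** For equal-length motifs,
$S_m(X, Y) = \sum_i S(X[i], Y[i])$ and
$$SP(M, M') = \frac{S_m(M, M')}{S_m(M, M)}.$$
Normalising by the *substituting* motif's self-score makes every motif its
own best substitute, with $SP(M, M) = 1$. Motif $M$ *can substitute* $M'$
when (1) lengths are equal, (2) every position-wise score
$S(M[i], M'[i])$ is non-negative, and (3) $SP(M, M') \ge T$ for a
user threshold $T \in [0, 1]$.

**Clustering and filtering.** Motifs are sorted by length (descending),
then $P_m$ (descending), then lexicographically. Each motif $M'$ is
assigned to the main motif $M$ with the highest $P_m$ among all motifs
that can substitute it ($M'$ itself always qualifies, so the assignment is
total); equal $P_m$ breaks to the lexicographically smaller motif, making
the clustering deterministic across platforms. A motif can be a member of
one cluster while being the main motif of another. Filtering keeps only
the main motifs; every removed motif remains substitutable by a retained
one, which is the information-preservation property the substitute-aware
context then exploits.

```{r example}
m <- load_substitution_matrix("BLOSUM62")
cl <- cluster_motifs(c("LLK", "IMK", "VMK", "GGP", "RI", "RV",
                       "RF", "RA", "PP"), m, T = 0.5)
cl
filter_main_motifs(cl)
```

## Choices where the design was open

- **"Positive" means strictly positive.** Zero scores are excluded from
  the conservation denominator; numerically they change nothing, the
  convention is fixed for clarity. Condition (2) of substitutability, by
  contrast, admits zero scores (it requires $\ge 0$).
- **SP normalisation.** Dividing by $S_m(M, M)$ rather than
  $S_m(M', M')$ is what makes a motif its own best substitute; both
  conventions reproduce the worked example above at $T = 0.5$, and the
  self-substitution argument fixes the former.
- **Printed precision is truncation.** Two-decimal comparisons truncate
  rather than round (0.87654 prints as 0.87). The package's tests compare
  at that precision via `floor(100 x) / 100`.
- **Tie-breaks.** Equal-$P_m$ candidates resolve lexicographically;
  sorting ties likewise. Rationale: byte-identical output across runs and
  platforms.
- **Worked-example threshold.** The nine-motif example reproduces for any
  $T \le 5/9$; examples and the example-based tests use $T = 0.5$. The
  production default stays at $T = 0.9$, the conventional setting for
  real corpora.
- **Anomaly.** The printed mutation probability of RF in the source
  example (0.72) disagrees with the calculus ($1 - (5/8)(6/10) = 0.625$)
  and coincides with RV's value, most plausibly a transcription slip; RF's
  cluster assignment (main motif RI) reproduces regardless, and RF is
  excluded from numeric example checks.

## Baseline encoders

- **N-grams**: all distinct length-$N$ windows, slid character by
  character (default $N = 3$).
- **Amino acid composition**: the 20 residue frequencies of a sequence
  (classic definition; sequence-order variants are out of scope).
- **Active motifs**: substrings of length $\ge$ `min_length` whose
  *activity* — the number of sequences containing a match within
  `mutations` Hamming substitutions — reaches `activity_pct` percent of
  the corpus (defaults: length 3, 25%, exact matching). Activity counts
  sequences across all families. Enumeration is capped with an explicit
  "too many attributes" error; the method is known to blow up on large
  heterogeneous corpora.
- **Discriminative descriptors**: per-family repeats (substrings of
  length 3–10 by default, present in at least two distinct sequences of
  the family, or twice within a single-sequence family), filtered by
  coverage (contained in $\ge \alpha$ of the family) and exclusivity
  (contained in $\le \beta$ of every other family; $\beta = 1$ disables
  the cross-family check), then pruned to minimal motifs — a motif is
  dropped when a proper substring of it is also retained for the same
  family. Defaults $\alpha = 0$, $\beta = 0$ yield family-exclusive
  substrings. The two filter conditions and the repeat definition are the
  package's documented reading of the DD scheme; they are validated by
  internal consistency (brute-force oracles), not against any external
  attribute counts.

Non-standard residue codes (B, Z, X, U, \*) act as motif separators
throughout: no extracted motif or matched window spans one. The repeat
finder itself is alphabet-agnostic (it is a generic string algorithm);
protein callers enable the separator rule.

## Context construction

Exact mode marks cell $(s, f)$ with 1 iff feature $f$ occurs as a
substring of sequence $s$. Substitute-aware mode — the DDSM rule — marks 1
iff any window of $s$ (same length as $f$, not spanning a separator) is
substitutable by $f$ under the matrix and threshold. Substitute-aware
presence therefore dominates exact presence cellwise. Presence scanning is
a naive sliding window; at the package's problem sizes this is exact and
fast, and any accelerated variant is contractually identical. Test
contexts must be built with the learning context's frozen feature list.
ARFF output encodes features as nominal `{0,1}` attributes (WEKA parity);
CSV output is RFC-4180.

## The synthetic fixture generator

`generate_fixture()` emulates the situation the method targets: distinct
families of otherwise-random sequences, each carrying family-specific
implanted motifs, a fraction of which appear as substituted variants.
Defaults — 3 families of 20 sequences of length 100 with one length-6
signature motif each — mirror a small multi-family corpus of distinct,
distant families. Variants are built by enumerating single-position
replacements with non-negative scores whose resulting $SP$ stays above the
configured threshold, applying one or two; each motif draws a small pool
of variants (default 2) that is reused across sequences, the way a real
mutated motif recurs within a family. A motif of fully conserved residues
admits no variant and raises an explicit error. Everything is a
deterministic function of the seed.

What the generator does *not* emulate: realistic residue background
frequencies, indels, length variation, shared domains between families,
and the weak homology structure of real corpora. Passing fixture tests
therefore demonstrates the algebraic and pipeline properties of the
encoders — recovery of implanted signals, feature-count reduction,
information preservation — not classification accuracy on real protein
datasets, which depends on external corpora and classifiers that are
deliberately outside this package's scope.

## Evaluation harness

`mav()` is the majority-class floor: 100 times the largest class share,
truncated to one decimal. `loo_nn()` is a deterministic leave-one-out
1-nearest-neighbour evaluation over binary contexts (Hamming or Jaccard
distance; distance ties resolve to the earliest instance in input order).
It is a reference harness for comparing encodings, not a re-implementation
of any external classifier suite; published accuracies obtained with
other classifiers are not comparable targets for it.

## Problem sizes and limitations

The test suite and examples run fixtures of 2–3 families with 4–8
sequences of length 30–50, and property checks over motifs of length 1–6;
brute-force oracles are exact at these sizes. The clustering is
$O(n^2)$ in the motif count within each length class and is intended for
the feature-set sizes DD filtering produces; very large motif sets would
need the approximate indexing that is explicitly out of scope. Gap-aware
substitution, non-integer matrices, and sequence-order composition
variants are likewise out of scope.
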