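---
title: "Methods: approximate homology mapping with sensitivity guarantees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: approximate homology mapping with sensitivity guarantees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepmap)
```

## Scope and model

`sweepmap` estimates the boundaries and identities of all local
alignments between long DNA sequences that satisfy two user requirements:
a minimum alignment length $l_0$ (bp) and a maximum per-base error rate
$\varepsilon_{\max}$ (identity $\ge 100(1-\varepsilon_{\max})$ percent).
It never computes base-level alignments; everything rests on k-mer
statistics under two modelling assumptions:

* alignment errors (substitutions and indels) occur independently and
  follow a Poisson process along the alignment, so the expected error
  count of a sub-interval is proportional to its length; and
* k-mers are treated as independent entities, so the number of sketch
  hashes shared between a fragment and its true mapping window can be
  modelled binomially.

Under the Poisson model, the Jaccard similarity of the k-mer sets of two
aligned sequences at error rate $\varepsilon$ is
$J(\varepsilon) = 1/(2e^{\varepsilon k}-1)$, with inverse
$\varepsilon(J) = -\tfrac1k \log\frac{2J}{1+J}$.  These closed forms are
implemented as `jaccard_from_error()` / `error_from_jaccard()` and are
mutual inverses to machine precision ($<10^{-12}$ across the domain, a
property the suite asserts on a 100-point grid).

## The pipeline

**Fragmentation.**  The query is tiled with non-overlapping fragments of
$l_0/2$ bp (`fragment_query()`; odd $l_0$ rounds down; a trailing
remainder is discarded).  Any true alignment of length $L \ge l_0$ fully
contains $n = \lfloor (L - l_0/2 + 1)/(l_0/2)\rfloor \ge 1$ fragments
regardless of its phase relative to the grid, which is what makes
end-to-end fragment mapping a complete seeding strategy.

**Sketching.**  Sequences are sampled by winnowing
(`winnow_minimizers()`): in every window of $w$ consecutive k-mers the
k-mer with the smallest canonical hash is kept.  Canonical hashing takes
the minimum of the hashes of a k-mer and its reverse complement, so
minimizers are strand-symmetric.  A fragment's sketch is its $s$ smallest
distinct minimizer hashes; the fraction of sketch hashes present in a
candidate window's minimizer set estimates $J$.  Duplicate minimizer
hashes within a fragment are counted once (set semantics) — the
multiplicity convention is not dictated by the model, and set semantics
keeps the estimator identical to the set-Jaccard containment it is tested
against.

**Fragment mapping.**  Matched reference positions of sketch hashes are
scanned with a sliding window of the fragment length.  The count of
*distinct* shared sketch hashes in a window is compared against the
tuned threshold $m$; each run of overlapping candidate windows is reduced
to the position maximising the Jaccard estimate (leftmost on ties), and
windows with $\hat J \ge \tau$ are emitted.  Strand is decided by
majority vote over the products of query- and reference-minimizer
strands.  Thresholding the distinct-hash count and thresholding $\hat J$
are the same comparison at two granularities, so the two classical
stages (coarse shared-count filter, then Jaccard evaluation) collapse
into one exact scan.

**Merging.**  Mappings of consecutive fragments $q_i,\dots,q_j$ on the
same reference sequence and strand merge into one segment when their
begin positions are monotone and adjacent gaps are at most $l_0$.  The
stated rule covers the forward orientation; for "−" strand mappings we
require monotonically non-increasing begins with the mirrored gap bound —
the rule must be orientation-symmetric or reverse-strand alignments could
never merge.  Segment boundaries are the first/last member offsets
extended by the fragment length; identity is the unweighted mean of the
member identities (members all have equal length, since tail fragments
are dropped) and the score is the identity fraction times the merged
query span, exactly.  When a fragment has several admissible
predecessors, the chain whose implied diagonal is closest is extended
(greedy); mappings never merge across reference sequences.

## Auto-tuning and the sensitivity guarantee

`auto_tune()` derives everything from $(l_0, \varepsilon_{\max})$:

| parameter | default | meaning / rationale |
|---|---|---|
| $k$ | 16 | k-mer length; large enough that random 16-mer collisions are negligible at genome scale, small enough to survive 20% divergence |
| $s$ | 200 | sketch size; binomial noise $\sqrt{J(1-J)/s}$ small enough for a ~1% identity resolution |
| $w$ | $\lfloor 2(l_0/2)/s\rfloor - 1$ | chosen so one fragment yields about $s$ minimizers (density $2/(w{+}1)$) |
| confidence | 0.90 | acceptance probability guaranteed for a borderline true mapping |
| $\tau, m$ | derived | $m = \max(1, q)$, $q$ the $(1-\text{confidence})$ quantile of $\mathrm{Bin}(s, J(\varepsilon_{\max}))$; $\tau = m/s$ |

With $X \sim \mathrm{Bin}(s, J(\varepsilon))$ the per-fragment mapping
probability is $p = P[X \ge m]$ and the seed sensitivity of an alignment
is $1-(1-p)^n$.  By construction $p \ge$ confidence at
$\varepsilon = \varepsilon_{\max}$, so the analytic floor over any grid
is at least 0.90 with the defaults; evaluated over
$\varepsilon \in (0, \varepsilon_{\max}]$ and 1–10 fragments it is
0.9133 for $\varepsilon_{\max}=0.10$ and 0.9217 for
$\varepsilon_{\max}=0.20$.

Two relaxation conventions are implemented because the exact convention
is a genuine free choice: the default one-sided quantile (above), and a
two-sided variant using the $(1-\text{confidence})/2$ quantile, which
relaxes further (floors 0.969/0.985).  The floor is convention-sensitive
at the $\pm 0.02$ level; the one-sided reading is the default because it
matches the plain meaning of "accepted with 90% confidence".

A consequence of relaxing $\tau$ below $J(\varepsilon_{\max})$ is that a
reported identity can fall slightly below the requested minimum — the
lower bound is $100(1-\varepsilon(\tau))$ rather than
$100(1-\varepsilon_{\max})$.  Clamping reported mappings at the nominal
threshold instead would silently forfeit the sensitivity guarantee, so
the relaxed bound is kept and documented.

## Filtering

Mappings are laid out as weighted intervals (scores as weights); a
segment is redundant iff at every one of its positions some strictly
higher-scoring segment covers it.  Equal scores never dominate each
other, so fully-overlapping ties all survive.  `plane_sweep()` solves
this exactly in $O(n\log n)$: endpoints are processed in ascending order
(insertions before removals at equal coordinates — intervals behave as
closed, so segments sharing only a boundary coordinate do overlap at
that event), the sweep status is an ordered set under (score, begin
position, id), and after each halting point the segments tied at the
maximum are marked good, descending from the maximum and stopping at the
first already-marked segment.  The id tiebreak is required for container
correctness; the (score, begin) order alone is a partial order.  Scores
are compared exactly (they are rational products of small quantities);
no epsilon is used.

`filter_map()` applies the sweep per query sequence on query-axis
intervals.  `filter_one_to_one()` then re-filters the query-pass
survivors per reference sequence on reference-axis intervals; the
sequential reading (second pass sees only survivors) is one of two
defensible readings of "followed by", and is the one implemented — it
guarantees the one-to-one output is a subset of the map output, which
the suite asserts.  The half-open mapping coordinates are converted to
closed intervals (`end − 1`) before sweeping so that abutting segments do
not count as overlapping.

## Synthetic data

The generators exist so every guarantee is testable without downloads.
`random_genome()` draws i.i.d. uniform bases; `mutate_sequence()` applies
independent per-position errors at rate $\varepsilon$ with a
substitution/insertion/deletion mixture of 80/10/10 by default (the
Poisson error model does not fix the mixture; 80/10/10 is a realistic
balance for long-read-corrected assemblies and is exposed as a
parameter); `plant_homologies()` embeds mutated (optionally
reverse-complemented) copies of reference loci between independent random
spacers and returns ground-truth intervals.  Recall is scored by the
overlap criterion used throughout: a truth locus is recalled when a
reported segment overlaps it on both query and reference axes with
matching strand.

What the simulations do *not* emulate: real repeat families (SINE/LINE
copies of sub-threshold length can inflate window Jaccard in real
genomes), GC skew and compositional bias, platform-specific error
profiles, and structural rearrangements within one alignment.  Passing
the recall tests therefore demonstrates the probabilistic model and the
implementation, not precision on repeat-rich genomes — precision there
is governed by the same k-mer statistics that admit dense short repeats.

## Numerical choices and degenerate inputs

* Hashes: fixed-seed splitmix64 finalizer over 2-bit-packed k-mers; the
  top 53 bits are exposed to R (exactly representable in doubles).
  Expected collisions among $10^4$ random 16-mers remain $\ll 1$.
* K-mers containing non-ACGT characters are skipped entirely (never
  encoded); an all-N fragment yields an empty sketch and is counted as
  skipped, not an error.
* Winnowing ties take the leftmost minimum; sequences holding fewer than
  $w$ k-mers are treated as a single window, so a length-$k$ sequence
  yields exactly one minimizer.
* $m$ and $w$ are clamped at 1 with a warning when the requirements are
  loose enough to relax them away.
* Candidate windows are clamped to reference bounds, so emitted
  coordinates never overhang a sequence end.
* Coordinates are 0-based half-open internally and in output (PAF
  convention); the tab layout carries 11 columns (names, lengths,
  intervals, strand, identity to 2 decimals, integer score).
* All generators are pure functions of their seeds and restore the
  session RNG state.

## Validation problem sizes

The suite validates the filter against a brute-force redundancy oracle on
1000 random instances of up to 500 intervals with deliberate score ties;
recall on 200 planted homologies of $2 l_0$ at $\varepsilon =
\varepsilon_{\max}/2$ ($l_0 = 5000$, $\varepsilon_{\max} = 0.10$, one
~4 Mb query against a ~2.4 Mb reference); and self-identity on a 100 kb
sequence.  These sizes exercise every code path at full statistical
strength while keeping the default suite near two minutes on one core.

## Known limitations

* Precision is bounded by k-mer statistics: dense exact repeats shorter
  than $l_0$ inside a window can qualify as matches (high estimated
  identity without a qualifying base-level alignment).  Downstream
  base-level validation is out of scope here.
* Identity estimates are slightly optimistic in the presence of indels
  (an indel disrupts fewer k-mers than its base count suggests).
* The merge rule chains greedily; pathological many-to-many fragment
  mappings on a repeat could be chained differently by an optimal
  chainer.
* Single-threaded reference implementation; performance engineering
  (threading, memory-mapped indexes) is deliberately not attempted.
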