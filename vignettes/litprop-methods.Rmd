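---
title: "Literature-based gene prioritization by network propagation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Literature-based gene prioritization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litprop)
```

## The problem

Only a small fraction of the ~1500 RNA-binding proteins (RBPs) in the human
genome have been genetically linked to amyotrophic lateral sclerosis (ALS),
yet mislocalization and aggregation of RBPs is a near-universal feature of
the disease. litprop implements a transparent, fully testable version of the
literature-based prioritization strategy used to predict new disease-gene
candidates from published abstracts alone: if the abstracts that mention a
candidate gene *talk about the same things* as the abstracts that mention the
genes already known to cause the disease, the candidate deserves a closer
look. The package is written for computational biologists who want to run,
audit, or stress-test that strategy end to end on their own corpora, and for
methodologists who want a reference implementation of its validation
statistics.

## The model

The pipeline has four stages, each behind its own class and function
surface.

**1. Mention annotation.** Documents (`Corpus`) are scanned against a gene
lexicon (`GeneDictionary`, symbol plus synonyms) with a longest-match,
non-overlapping, word-boundary scan. Two numerical-text conventions matter
and are deliberate:

* Surface forms of five or more characters match case-insensitively;
  shorter forms match case-sensitively. Short gene symbols are ordinary
  English letter strings (ANG, TIA1) and would otherwise fire inside
  unrelated words; long forms like "hnRNPA2B1" are unambiguous at any
  casing. The boundary rule forbids flanking letters or digits but allows
  internal hyphens, so "TDP-43" is a unit.
* A surface form attached to more than one gene is *ambiguous*. The default
  `strict` policy records such mentions but attributes them to no gene.
  This is a direct response to a documented failure mode of shared
  nomenclature: hnRNPH-style synonyms shared between HNRNPH1 and HNRNPH2
  can silently transfer one gene's disease literature to the other and
  manufacture a false positive. The alternative `first-gene` policy exists
  solely to let users reproduce that failure mode and measure its effect.

**2. Semantic profiles.** For each gene, the tokens of every abstract with
an unambiguous mention are pooled into a term vector (`EntityTermMatrix`).
Tokenization lowercases, splits on anything that is not a letter, digit or
internal hyphen, drops tokens under two characters, removes a fixed,
versioned English stopword list (`litpropStopwords()`, version
`r attr(litpropStopwords(), "version")`), and removes the gene's *own*
surface forms — a profile should describe the contexts a gene appears in,
not its name. Other genes' names are kept: co-mention is genuine signal.
The default weighting is sublinear TF-IDF,
$w_{gt} = (1 + \log c_{gt}) \cdot \log(N / n_t)$,
with $c_{gt}$ the pooled count of term $t$ for gene $g$, $N$ the number of
profiled genes and $n_t$ the number of profiles containing $t$; a term that
occurs in every profile carries no information and gets weight zero. Raw
summed counts are available as `weighting = "raw"`. TF-IDF cosine is the
standard transparent surrogate for "semantic similarity over abstracts";
nothing in the pipeline depends on this choice beyond the similarity values
themselves.

**3. Similarity graph.** `similarityMatrix()` computes cosine similarity
between all profile pairs (`SimilarityMatrix`): entries in $[0, 1]$ because
weights are non-negative, zero diagonal (no self-loops; distance is
$1 - s$), and zero similarity for any pair involving an empty profile.
The full dense matrix is kept — every gene is related to every other —
rather than a sparsified k-NN graph.

**4. Graph diffusion.** Candidates are ranked by random walk with restart
from the seed (known) set. With $P$ the column-normalized similarity matrix
and $p_0$ uniform over seeds, the score vector is the fixed point of

$$s \leftarrow \alpha P s + (1 - \alpha) p_0 ,$$

equivalently $s = (1-\alpha)(I - \alpha P)^{-1} p_0$. Columns with zero
similarity sum (isolated genes) are *dangling*; their outgoing mass
teleports back to the seed distribution, which conserves total mass without
biasing the walk toward isolated nodes. Scores are a probability
distribution over all genes (they sum to 1), so with $n$ around 1500 genes
individual graph-diffusion (GD) scores sit around $10^{-3}$–$10^{-4}$,
which is the magnitude a mass-normalized diffusion should produce at that
problem size. Seeds keep their scores internally but are excluded from the
candidate ranking; candidate ties are broken lexicographically so rankings
are bit-reproducible.

Defaults: $\alpha = 0.7$, L1 convergence tolerance $10^{-9}$, at most 1000
iterations. $\alpha$ controls how far mass diffuses from the seeds before
restarting; 0.7 is the common middle ground in network-propagation practice
(the ranking is insensitive over a broad range because cosine similarity,
not path length, dominates this graph). Iteration failure is an error that
reports the last residual, never a silent partial result.

## Validation statistics

`looCrossValidation()` removes each known in turn, re-diffuses with the
remaining seeds over the *same* similarity matrix (profiles are not rebuilt
per fold), and records the held-out gene's 1-based rank among the
candidates plus itself.

**AUC.** `aucFromRanks()` reads the held-out ranks as the positions of the
positives in one pooled positive-plus-negative ranking and returns the
fraction of concordant (positive, negative) pairs — the Mann–Whitney
statistic, equal to the trapezoid-rule area under the pooled ROC step
curve. For the reference ranks shipped as `alsLooRanks()` this evaluates to
`r round(aucFromRanks(alsLooRanks(), 1467), 4)`. Pooled ranks from
independent folds can tie; the count of negatives above a positive is then
clamped to its feasible range. The brute-force pair-counting oracle in the
test suite is the authoritative definition; the closed form is an
optimization.

**Wilcoxon.** `wilcoxonOneSided()` tests whether the knowns' scores exceed
the candidates' via the rank-sum $W$ with a continuity-corrected normal
approximation,
$z = (W + 0.5 - n_1(N+1)/2) / \sqrt{n_1 n_2 (N+1)/12}$,
lower tail. An exact method enumerates all $\binom{N}{n_1}$ placements for
$N \le 25$; the two agree within 0.02 absolute for $n_1 \ge 2$ and
$N \ge 10$ (with a single known the exact null has only $N$ support points
and no normal approximation is that close — the test suite documents the
measured worst cases).

**Fisher enrichment.** `fisherExactGreater()` computes the upper-tail
hypergeometric probability $P(X \ge a)$ in log space via `lchoose`, checked
against full-support enumeration and `stats::fisher.test` in the tests.
`buildTopKTable()` assembles the top-$k$ enrichment table ("how likely is
it that $a$ of the top $k$ candidates are truly disease-linked if $K$ of
$N$ are"). `thresholdFisherMedian()` applies the same test at every
distinct held-out rank threshold and reports the median p value; because
folds rank independently, more than $r$ knowns can occupy ranks $\le r$,
and the candidate cell of the table is clamped at zero in that case.

**Retrospective evaluation.** `retrospectiveRun()` slices the corpus at a
cutoff date, annotates and profiles only the slice, seeds with the genes
known *at that date*, and reports where later-discovered genes rank.
Cutoffs are inclusive ("published through 2012" is the slice at
2012-12-31), and bare-year dates normalize to December 31 for the same
reason. Later positives with no pre-cutoff mention are reported ineligible
rather than force-ranked, mirroring how eligibility filtering ("at least
one abstract") precedes ranking in practice. Perturbing any post-cutoff
document leaves the report bit-identical — the test suite asserts this
leakage property directly.

## The synthetic corpus generator

Real biomedical corpora and proprietary annotation systems are not
reproducible test substrates, so `simulateCorpus()` generates corpora whose
planted structure is exactly the structure the method claims to exploit:

* a background vocabulary and a disease-topic vocabulary;
* documents about a *positive* gene draw each token from the topic pool
  with probability `signalDelta`, from the background otherwise; background
  genes draw background tokens only;
* every document literally contains a surface form of its gene (plus, with
  probability `comentionRate`, a form of a second gene), so the annotator
  is exercised end to end, not bypassed;
* a fraction `discoveryFraction` of positives get a "discovery date" in the
  second half of the date range: their earlier documents are topic-free,
  so a pre-discovery corpus slice carries only the weak co-mention signal
  for them — the substrate for retrospective validation;
* `ambiguityPairs` shared synonyms reproduce the hnRNPH-style collision.

The co-mention partner is *topic-similar*: same class (positive with
positive) when a topic is planted, uniform over all genes when
`signalDelta = 0`. With no planted topic there is no disease cluster, and
class-structured co-mention would itself manufacture one, making the
no-signal null fail by construction.

Defaults — 200 genes, 20 positives, topic weight 0.8, about 10 abstracts of
80 tokens per gene (floored at one document so every gene is rankable),
2000 background and 150 topic terms, 20% co-mention, dates spanning
2000–2015 — are the package's standard study conditions, sized for test
power: strong enough that a correct pipeline separates the planted cluster
essentially perfectly, small enough that a full
simulate–annotate–profile–diffuse–validate cycle takes a few seconds. The
acceptance checks run the high-signal recovery at these conditions, the
no-signal null over 20 seeds (mean leave-one-out AUC at chance level), and
the retrospective run at `discoveryFraction = 0.3`.

What the generator does *not* emulate: real English, MeSH/author metadata,
citation structure, secular trends in vocabulary, nonstationary publication
rates, or the long-tailed document-per-gene distribution of a real corpus.
Passing on synthetic corpora therefore demonstrates that the pipeline's
machinery is correct and leak-free — not that TF-IDF cosine is a good model
of biomedical semantics; that judgment has to come from the reference
statistics recomputed from the published validation numbers.

## Numerical and degenerate-input choices

* All randomness in the generator flows from one integer seed; identical
  parameters give byte-identical corpora.
* Diffusion convergence is measured in L1; scores sum to 1 within $10^{-9}$
  by construction (column-stochasticity plus teleport).
* Zero-profile genes are allowed (warned, not errored): they get zero
  similarity everywhere and become dangling columns.
* Candidate ties (exactly equal GD scores) break lexicographically by gene
  id, stated rather than incidental, so ranks are stable across platforms.
* Empty corpora, header-only dictionaries and empty rank lists are
  legitimate degenerate inputs with defined results; malformed files
  (missing keys, unparseable dates, duplicate ids) are errors that cite the
  offending line or field.

## Known limitations

* The annotator is a deterministic dictionary scanner; it does not attempt
  learned named-entity recognition, abbreviation expansion, or species
  disambiguation.
* Profiles are bag-of-words; no embeddings, topic models, or syntax. A gene
  whose disease link is expressed through function rather than shared
  vocabulary (the DDX58 problem: a gene semantically unlike the seed set
  ranks low regardless of its true status) is invisible to this method by
  design.
* The similarity matrix is dense; corpora with many tens of thousands of
  entities would need a sparse or blocked implementation.
* Published GD scores from proprietary Medline-scale systems are not
  reproducible here; the package reproduces the validation arithmetic on
  the published ranks and the method's behavior on controlled corpora.
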