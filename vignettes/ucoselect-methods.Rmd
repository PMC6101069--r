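---
title: "Methods and design of ucoselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of ucoselect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and design decisions behind
`ucoselect`: what each stage computes, which defaults matter and why, what
the synthetic-data generators do and do not emulate, and where the design
was genuinely open and a choice had to be made.

## Taxonomy-based selection

The taxonomy stage parses the NCBI taxdump dialect (`nodes.dmp` /
`names.dmp`, pipe-delimited) into a rooted tree whose single root is the
node with `parent == self`. Parsing validates structure explicitly:
unresolvable parents, multiple roots and parent cycles are errors naming
the offending row, because a silently malformed taxonomy corrupts every
downstream score.

**Depth convention.** Depth counts *edges from the root, root = 0*. This
has to be stated because taxonomy distances are sometimes counted in nodes;
all scores in this package use the edge convention. The relatedness score
of a candidate is the depth of its lowest common ancestor (LCA) with the
query. The taxonomy tree carries no meaningful branch lengths, so only this
topological depth is defensible: a deeper LCA means the pair diverges lower
in the tree. Whether the candidate's *own* depth should enter the score is
an open question with no ground truth to settle it; we use pure LCA depth,
which is the only reading consistent with "higher score = deeper shared
node", and document rather than assert it.

**Constraints.** Candidates are restricted to those sharing the query's
phylum-rank ancestor. Lineages with no phylum-rank node exist (protist
lineages, notably), so a query without one skips the constraint with a
warning instead of failing. The selection window defaults to 3–5 species: a
shortfall below the minimum is reported with a warning flag, not an error,
because a thin result is still actionable. Score ties break by ascending
taxon id, making the ranking a pure function of the tree — invariant to
candidate input order.

A query species absent from the taxonomy raises a typed error
(`uco_path_error`) directing the caller to the sequence-based route; that
is a routing signal, not a failure.

## The alignment primitive

All sequence comparison runs through one primitive: Smith–Waterman local
alignment under BLOSUM62 with affine gaps, gap open 11 / extend 1 (a gap of
length L costs 11 + L — the convention of protein BLAST defaults). The
implementation wraps `Biostrings::pairwiseAlignment`; the test suite checks
it against an independently coded dynamic-programming oracle on random
peptide pairs, exactly. Alignments with no positive-scoring cell report
score 0 with empty spans. Word size, seeding and other database-scale
heuristics are deliberately out of scope: at the scale this package
operates (hundreds of sequences), exhaustive pairwise alignment is both
affordable and exact. Externally computed BLAST tabular hits (outfmt 6) can
be substituted through `parse_blast_tab()` + `best_hits()`.

**E-values.** Significance uses the Karlin–Altschul form
`E = K·m·n·e^(−λS)` with the ungapped BLOSUM62 constants K = 0.041,
λ = 0.267. These approximate gapped BLAST statistics; that is acceptable
here because nothing downstream consumes the magnitude of E — only the
conventional `E < 1e-10` acceptance threshold matters, and at that
stringency the ungapped approximation and gapped statistics agree on which
hits are genuine homologs versus noise.

**Six-frame translation** uses the standard genetic code with no
initiator-codon special-casing (a frame is not a gene model), emits stop
codons as `*`, and does not split frames at stops: downstream alignment is
local, so stops simply score negatively, mirroring how translated-search
tools behave at this scale.

## UCO-based selection

Ultra-conserved orthologs (UCOs) — canonically a panel of 357 single-copy
genes conserved across most eukaryotes — serve as a fixed yardstick: each
candidate proteome is searched with every UCO, and the best hit passing
`E < 1e-10` becomes that species' *representative* protein for the gene.
Completeness (UCOs found / 357) is reported per species, since a reference
with many missing UCOs likely has thin annotation generally.

Query contigs are assigned at most one UCO each (best score over all six
frames and all UCO proteins, threshold as above). Each assigned contig then
votes: its in-frame peptide is aligned against every species' representative
for that UCO, and the best-scoring species receives the vote.

Two conventions here were genuinely open:

* **Votes, not summed bit scores.** The per-species score is the *count* of
  contigs won. Counts are robust to UCO length variation (a long gene
  cannot dominate the ranking) and make the score interpretable as "mapped
  UCOs". Both raw votes and the count of distinct UCO ids won are reported,
  since fragmented assemblies can yield several contigs per UCO.
* **Fractional ties.** A contig tying across t species contributes 1/t to
  each, preserving the invariant that votes sum to the number of voting
  contigs (tested property).

`top_k` defaults to 3 selected species — enough to fill annotation gaps,
few enough to keep downstream alignment affordable.

## Mantel validation of UCO distances

Whether different UCO genes tell a *consistent* story about species
relatedness is quantified by correlating their distance matrices. The
distance is `1 − identity/100` from the pairwise local alignment of the two
species' representatives; matrices are symmetric with zero diagonal by
construction. Multiple-alignment-derived distances would be an alternative;
pairwise identity was chosen because it reuses the package's single
alignment primitive, is exact at this scale, and the Mantel statistic only
consumes the relative ordering of distances.

The statistic standardizes the upper-triangle off-diagonal entries. With m
such entries, `r = Σ x̃ᵢ·ỹᵢ /(m−1)` where `x̃` is the z-score with the
(m−1)-divisor standard deviation. The normalization is *defined over the m
triangle entries* (not the matrix dimension): this is the choice that makes
`r(x, x) = 1` exactly and bounds r in [−1, 1], which any identity-scaled
correlation must satisfy. Different UCOs cover different species subsets,
so each pair of matrices is first restricted to its shared species; fewer
than 3 shared species leaves the correlation undefined (error for a single
pair, `NA` row in the batch sweep — the batch table always has exactly
`choose(m, 2)` rows). Zero variance in a restricted matrix is likewise an
explicit error, not a silent 0 or NaN.

Significance uses a one-tailed (greater) permutation test: simultaneous
row/column permutation of one matrix, with the observed statistic included
in the count — `p = (1 + #{r_perm ≥ r_obs})/(B + 1)`, so the attainable
floor is `1/(B+1)` and p is uniform under the null (tested by
Kolmogorov–Smirnov over 200 seeded replicates). The seed is a required
argument: permutation p-values without a recorded seed are not
reproducible. The batch all-pairs sweep is vectorised (masked cross-product
sums over stacked triangles), which keeps a full 357-matrix panel — 63,546
pairs — under a second; correlation coefficients are reported with p left
to explicit per-pair calls, since at tens of thousands of pairs the
coefficient, not each permutation p, is the object of interest.

## Annotation transfer and enrichment

Each contig is annotated, per selected species, by its best translated hit
passing the e-value threshold ("best hit = ortholog" — the standard, if
approximate, transfer rule; no orthology arbitration is attempted when
species disagree). GO terms and pathway ids attach from per-species
gene-to-term tables, and merging takes the union per contig across species.
Union semantics give the package its central monotonicity property: adding
a reference species can never shrink the annotated-contig count or any
merged term set (tested on random fixtures).

Enrichment of a DE contig list is the hypergeometric upper tail
`P(X ≥ k)` with `X ~ Hypergeom(N, K, n)`, computed via `phyper`. Two
conventions:

* **Background universe** = contigs with ≥ 1 merged annotation *of the
  tested kind* — the standard enrichment practice. Using all contigs
  (mostly unannotatable ones) would deflate every p-value with genes that
  could never appear in the DE-by-term intersection. DE ids outside the
  background are dropped with a warning.
* **Significance flags.** Raw p < 0.05 is the headline flag, and
  Benjamini–Hochberg adjusted values with their own flag are always
  reported alongside, because dozens to hundreds of terms are tested and
  uncorrected significance alone is not defensible. Over-representation
  only; under-representation is out of scope.

GO terms are treated as a flat vocabulary — no propagation to ancestor
terms. Propagation changes K and k for every ancestor and would need the GO
graph as an input; with transfer-based annotation of a non-model species
the flat test is the conservative, assumption-free default.

## Synthetic data: what it does and does not emulate

The generators produce every input with recoverable truth, from a single
seed (all randomness is routed through one seed argument; no global RNG
state leaks):

* `simulate_taxonomy` — random rooted trees with a phylum level,
  serialisable to taxdump and re-parseable identically.
* `simulate_proteomes` — one random ancestral protein per UCO, mutated
  independently along each edge with per-site probability `rate`
  (optionally per-edge rates, e.g. a star tree with 2%/10%/30% branches).
  Replacement is uniform over the 20 amino acids — so the realised
  divergence per edge is `rate·19/20`, and divergence accumulates along a
  path as independent edge events (≈ rate × path length for small rates).
  No rate matrix, no indels, no site heterogeneity: the pipeline exploits
  only the *ordering* of identities by tree distance, and the uniform model
  preserves exactly that.
* `simulate_transcriptome` — contigs as codon back-translations (uniform
  synonymous codon choice, standard code) of random protein fragments on
  random strands, plus a DE list drawn with weight `fold` for contigs whose
  source gene carries a planted term.

Default study conditions, chosen once as representative of a small
planted-truth experiment and used unchanged by tests and the acceptance
script: planted divergences 2%/10%/30% for recovery fixtures (a clearly
ordered near/mid/far design), 15 UCOs of 60–90 residues and 15 contigs of
40–60 residues per recovery fixture, 20 seeds; enrichment fixtures with 120
genes, a 20-term vocabulary, a planted term on 20% of genes at fold 5, DE
fraction 0.25, 20 seeds; Mantel panels of 8 species × 30 UCOs at rate 0.06.

What passing these tests shows: the machinery recovers planted truths under
a clean substitution model. What it does not show: robustness to indels,
assembly chimerism, contamination, paralog confusion, codon bias or
incomplete taxonomies in real data — none of which the generators emulate.
Real-data behaviour is bounded by the quality of the reference proteomes
and annotation tables supplied.

## Numerical and degenerate-input conventions

* Deterministic tie-breaks everywhere: ascending taxon id (taxonomy
  ranking), ascending subject id after e-value (best hits), fractional
  votes (UCO ranking), ascending term id at equal p (enrichment). Outputs
  are invariant to input order and byte-identical across reruns.
* Degenerate inputs are explicit: empty proteome → completeness 0 with a
  warning; <2 species for a distance matrix → skip with warning; <3 shared
  species → error (single pair) or NA (batch); zero-variance matrix →
  error; empty DE list → error; DE = background → all p = 1 (a correct,
  if useless, answer).
* Sequences shorter than one codon translate to six empty frames with a
  warning rather than an error, so contig sets with stray fragments do not
  abort a run.
* The pipeline (`run_pipeline`) is a pure function of (inputs, config,
  seed); reports are TSV + JSON with frozen column orders to support
  diff-based testing.

## Known limitations

* The built-in aligner is exhaustive: suitable for hundreds of proteins per
  species, not for searching millions of sequences. For database-scale
  work, run BLAST externally and feed the tabular output in.
* E-values use ungapped constants (see above); treat them as thresholding
  devices, not publishable statistics.
* LCA-depth scores are only comparable within one taxonomy snapshot;
  published example scores from any given era's database are not expected
  to reproduce against a different snapshot, and the same holds for UCO
  vote counts against different proteome releases.
* Annotation transfer inherits every bias of best-hit orthology; merged
  multi-species annotation mitigates missingness but cannot correct
  wrong annotations in a reference.
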