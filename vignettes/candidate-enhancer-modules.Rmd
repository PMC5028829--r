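---
title: "Detecting conserved clusters of pigmentation TF binding sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting conserved clusters of pigmentation TF binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhancerscan)
```

## The problem and the model

Melanocyte gene expression is controlled by a small network of transcription
factors — CREB, FOXD3, LEF1, MITF, POU3F2 and USF1 — whose binding sites tend
to occur in compact combinatorial clusters (cis-regulatory modules) in the
promoter-proximal regions of pigmentation genes. `enhancerscan` detects
candidate modules in the 1500 nucleotides immediately upstream of a gene's
transcription start site in three steps:

1. **Scanning.** Every window of every catalog pattern length, on both
   strands, is scored against the pattern's IUPAC consensus. The score is a
   *percent dissimilarity*: the fraction of positions whose base falls
   outside the consensus class at that position, times 100. Windows at or
   below the threshold (default 15%) become binding-site hits. This is a
   deliberate, exactly reproducible stand-in for proprietary
   position-weight-matrix dissimilarity scores: every position carries
   uniform weight, and a window scores 0 exactly when it is a concrete
   instance of the consensus.
2. **Collapsing.** Matrix libraries store many variants of one factor's
   site, so a single genomic site yields several overlapping hits of the
   same class. Overlapping same-class hits are collapsed to one
   representative (lowest dissimilarity, then leftmost, then longest).
   Different classes are never merged: a shared E-box bound by both MITF
   and USF1 is two sites, and that overlap is itself biologically
   informative.
3. **Cluster detection.** Per region, a 200-nt window slides at 1-nt steps;
   a window qualifies if its fully contained (collapsed) hits span at least
   two distinct factor classes. The qualifying window with the most sites is
   selected (ties break to the leftmost, i.e. most distal, window), its hits
   are removed, and the search repeats until three modules are found or no
   window qualifies. Reported intervals are trimmed to the minimal span
   covering the member sites.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `max_dissimilarity` | 15 % | scan acceptance threshold; at 15%, a 6-mer E-box must match exactly, a 7–11-mer tolerates one mismatch, a 14-mer two |
| `window_length` | 200 nt | cluster search scale; the biological prior is that cooperating sites sit within a few hundred bases |
| `clusters_per_region` | 3 | greedy selection depth per upstream region |
| `min_distinct_tfs` | 2 | combinatorial qualification: a module must involve at least two different factors |
| `trim_to_span` | `TRUE` | report the minimal interval covering member sites rather than the fixed window |

The FOXD3 entry of the packaged catalog is a generic forkhead-core
placeholder (`RTAAAYA`): the literature compilation behind the catalog
reports no FOXD3 binding sequence, so the entry is flagged
`is_paper_sourced = FALSE` and is user-replaceable
(`pigment_catalog(foxd3_pattern = ...)`). SOX10 patterns from the same
compilation ship with the catalog but are disabled by default, because
SOX10 is not part of the scanned six-factor set.

## Design choices where the design was open

* **Coordinates.** Positions are 1-based and inclusive on the forward
  strand, with position 1 the most distal base of the upstream window and
  position 1500 abutting the TSS. The orientation convention is recorded in
  run metadata (the resolved config written next to every run) so it can be
  flipped if region FASTA files follow the opposite convention.
* **Palindromes.** A reverse-strand match of the same pattern and class
  over the identical span would double-count a single physical site, so it
  is reported once, on `+`.
* **`N` handling.** `N` bases belong to no IUPAC class and never match,
  a conservative choice that favors precision over recall.
* **Window width.** The search window is fixed at 200 nt and the report is
  trimmed to the member span. This gives one free parameter instead of an
  unspecified variable-width search while still producing the variable
  printed interval widths that practitioners expect.
* **Exclusion rule.** After a module is selected, hits *overlapping* its
  search window (not only those inside it) are removed before the next
  round. Under this reading the reported trimmed intervals of one region
  provably never share a base; later windows may still abut earlier ones.
* **Missing identity cells.** Ortholog identity matrices store absent
  orthologs as missing (`NA`), never as 0% — an absent sequence is not a
  maximally divergent one. Heat-map exports emit the literal `NA` token.
* **Range summaries** are always computed from the matrix itself
  (`range_summary()`), so any externally stated range can be audited
  against the packaged values.

## What the synthetic generator emulates

`generate_study()` reproduces the statistical structure the detector
assumes, with planted ground truth:

* nine 1500-nt regions (named after the nine pigmentation target genes)
  of uniform A/C/G/T background;
* three planted 200-nt windows per region, pairwise separated by more than
  200 nt, each carrying 2–5 sites of *distinct* factor classes; the first
  and last site of each cluster anchor near the window edges so the cluster
  occupies most of its window;
* two same-class decoy sites per region in the 5′ dead zone, more than
  200 nt from any window — close enough to form a two-site window, but of
  one class only, exercising the `min_distinct_tfs` rejection path;
* a rejection step that rescans the background after planting and redraws
  any stretch that produced an accidental catalog hit outside the planted
  windows (bounded rounds), making "no hits outside the planted structure"
  an invariant rather than a probability;
* protein ortholog families: one random 300-residue reference per gene,
  mutated per species at fixed substitution rates (0.06–0.26, chosen to
  span the 74–94% identity range typical of reptile-to-mammal ortholog
  comparisons), with no indels.

One caveat is intrinsic to the catalog, not the generator: factor classes
share patterns (CATGTG is both an MITF and a USF1 site, and E-box cores
nest inside the longer M-box patterns), so a planted MITF M-box necessarily
also yields a USF1 hit at the same span. The generator's truth table
therefore guarantees a two-sided invariant — every planted site is
recovered at its exact span and class, and no hit falls outside planted
windows or decoy spans — rather than naive set equality of hits and
planted records.

What passing tests on synthetic data do **not** show: real upstream regions
have non-uniform composition, repeats and CpG structure, so false-positive
rates on genomic sequence will be higher than on rejection-cleaned
background, and the planted-recovery guarantees say nothing about
sensitivity to sites diverged beyond the 15% threshold.

## Numerical choices and degenerate inputs

* Threshold comparisons are integral: a window passes when
  `100 * mismatches <= threshold * pattern_length` (with a 1e-9 guard), so
  no floating-point boundary case can flip a hit.
* Greedy window search only evaluates offsets where a hit enters or leaves
  the window — the objective is piecewise constant in between — and the
  unit tests cross-check this against exhaustive enumeration of every
  offset.
* Empty inputs are legal everywhere downstream of scanning: no hits means
  no modules, an empty module table lays out an empty track, and a region
  shorter than every pattern scans to an empty hit table (scanning an empty
  *string* is an error).
* Protein alignment uses BLOSUM62 with affine gaps (open 11, extend 1),
  the common defaults for protein searches; identity is matches over
  alignment columns. Exact reproduction of any particular alignment
  service's best-hit identities is explicitly not a goal.
* All randomness flows from one integer seed; per-region and per-family
  substreams are derived at fixed offsets, so studies regenerate
  byte-identically on any platform.

## Problem sizes used in the tests

The shipped test-suite exercises: oracle equivalence of the scanner on
random regions up to 200 nt against brute-force expansion matching;
exhaustive-versus-greedy window agreement for up to 30 hits; planted-cluster
recovery (interval Jaccard at least 0.5 against every planted window, and
exact cluster-count agreement) across 20 independently seeded default
studies; and identity-rate recovery at substitution rates 0.05, 0.1 and 0.3
with 300-residue proteins. These sizes were chosen as the smallest at which
each property is meaningfully stressed.

## Worked example

```{r example, eval = FALSE}
run <- run_pipeline(run_config(out_dir = tempfile(), seed = 42,
                               log_level = "quiet"))
glance(run)   # 27 modules over 9 regions, 3 per region
tidy(run)     # per-region module/site counts

# visualize one region
track <- layout_region(
  run$modules[run$modules$region_id == "TYR", ],
  hits = run$collapsed[run$collapsed$region_id == "TYR", ]
)
autoplot(track)
```

## Known limitations

* The uniform-mismatch dissimilarity treats all consensus positions as
  equally informative; a trained position weight matrix would not.
* FOXD3 detection rests entirely on a placeholder consensus.
* No enrichment p-value is attached to modules; the qualification rule
  (two or more distinct factors in 200 nt) is a hard filter, not a test.
* Cross-species conservation is addressed only at the protein level
  (ortholog identity); upstream regions themselves are not aligned across
  species.
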