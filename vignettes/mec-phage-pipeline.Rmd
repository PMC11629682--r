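---
title: "Methods: phage-host association analysis for MEC metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phage-host association analysis for MEC metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the models, parameter choices and design decisions
behind `mecphage`, in the spirit of the methods sections of mature
community-analysis packages. Nothing here asserts an empirical result that
the test suite does not itself compute.

## The analysis problem

Microbial electrolysis cells (MECs) host electrode biofilms of
electroactive bacteria and methanogenic archaea. Metagenomic sequencing of
such reactors yields two datasets: genome bins from the prokaryotic
fraction and contigs from the filterable virus-like-particle (VLP)
fraction. Three kinds of evidence link a phage to a prokaryotic host:

1. **Prophage** — a temperate phage sequence found inside a host bin;
2. **Induced prophage** — that prophage additionally detected among the
   free VLP contigs, suggesting active induction;
3. **CRISPR match** — a spacer from a host CRISPR array matching a phage
   protospacer, recording a past infection.

`mecphage` takes the post-assembly artifacts (contigs plus quality,
lifestyle and count tables produced by external tools) and computes species
clusters, association networks, electrode-affiliation calls, and
Hill-number community statistics.

## Sketch ANI and clustering

Average nucleotide identity is estimated Mash-style: canonical k-mers
(lexicographic minimum of forward and reverse-complement 2-bit encodings,
k = 17, ambiguous bases skipped) are hashed and the bottom 1000 hashes
kept. Jaccard similarity `J` from the merged-sketch comparison gives
`ANI = 100 (1 + ln(2J/(1+J))/k)`, clipped to [0, 100] with `J = 0` mapped
to 0.

*Hash.* R has no native 64-bit integers, so the hash is an affine map
`(a·code + c) mod m` with `m = 9007199254740881` (the largest prime below
2^53), `a = 387421`, `c = 271828182`. Every product stays below 2^53, so
the computation is exact in doubles; a 53-bit hash space is ample for
desk-scale k-mer sets. This is a deliberate deviation from the customary
64-bit MinHash.

*Clustering.* Bins (contigs joined by N-runs so no chimeric k-mers form)
and phage contigs are clustered by average-linkage hierarchical clustering
on `d = 1 − ANI/100`, cut at 0.05 — mirroring dRep's secondary clustering
at the 95% species boundary. Cluster ids are assigned by each cluster's
lexicographically smallest member, so memberships are invariant to input
order. Representative selection uses dRep's default prokaryote score
(`completeness − 5·contamination + 0.5·log10 N50`) and highest CheckV
completeness for phages; ties break by total length, then id.

*Caveat.* Jaccard-based ANI is depressed when two genomes are incomplete:
two 55% truncations of the same genome share only ~30% of their k-mer
union, giving sketch ANI near 96 rather than ~99.5. The default synthetic
completeness range (55–100%) keeps within-species pairs above the 95%
threshold; much more fragmented real bins would need alignment-based ANI,
which is out of scope.

## CRISPR detection

Detection reimplements the CRT/MinCED strategy per contig: scan for an
exact 8-bp seed recurring at spacings of 49–97 bp (one repeat plus one
spacer under the CRT defaults: repeats 23–47 bp, spacers 26–50 bp), chain
recurrences into candidate arrays, extend repeat boundaries, and validate
(≥ 3 repeats, length bounds, mean pairwise repeat identity ≥ 0.9, mean
pairwise spacer identity ≤ 0.62). Overlapping candidates resolve by more
repeats, then longer span, then smaller start. Detection is strand-naive:
an array on the reverse strand is reported as its reverse-complemented
repeats at mirrored coordinates.

*Boundary extension.* A plain agreement-fraction threshold cannot both
tolerate isolated point substitutions (one dissent among n instances) and
avoid creeping into spacers by chance agreement when n is small (for n = 4
the probability that three of four random bases coincide is ~0.2 per
column). The implemented rule extends a boundary when a column agrees
fully, or when exactly one instance dissents (n ≥ 4, agreement above the
`extension_agreement` floor of 0.75) *and the next column out agrees
fully*. Chance agreement then almost never extends a boundary, while an
isolated substitution does not truncate the repeat.

No Cas-gene validation is attempted; the evidence standard is the array
alone. Arrays are detected per contig, not on bin concatenates, which
cannot create chimeric arrays across contig joins.

## Homology operations

*Prophage regions.* Each retained phage contig's k-mer set is matched
against each bin contig. Matching positions are clustered (gap ≤ 500 bp);
a cluster is reported when its span is ≥ 5 kb (the same threshold as the
phage length filter) and its match density is ≥ 0.5, which is the windowed
containment criterion expressed per cluster. Region identity is
approximated from k-mer match density as `100·density^(1/k)`. This
homology-to-known-phage approach replaces gene-content predictors
(VIBRANT/PhageBoost), which are consumed as metadata instead; externally
produced prophage annotations can be substituted upstream.

*Induction.* A prophage region matches a VLP contig when sketch ANI ≥ 95
and the matched-region coverage of the shorter sequence in the longer is
≥ 0.8. Coverage — the fraction of the shorter sequence blanketed by
clusters of matching k-mers — rather than raw k-mer-set containment is
used because uniform substitutions at 2% divergence drop raw containment to
~0.7 even though the sequences are homologous end-to-end; coverage stays
near 1 until homology actually ends. The 95/0.8 pair is this package's
operationalization of "also detected among the VLP", which has no published
threshold.

*Spacer matching.* Full-length ungapped scan of both strands with at most
one substitution (default), no indels, every placement reported, N never
matching. This is nucleotide-space matching (SpacePHARER works in
translated space) — transparent and exhaustively checkable against a naive
sliding-window oracle, at the cost of lower sensitivity to diverged
protospacers.

## Association network

Prophage edges require the phage species to be temperate under a logical OR
across whichever lifestyle predictor columns are present, applied at
species level (any member contig, any predictor); virulent-by-all regions
are excluded and logged. Induction promotes an existing prophage edge by
adding `induced_prophage` evidence; an induction match without a prophage
edge is logged as an orphan, never an edge. CRISPR edges collapse all
supporting spacer hits per (host, phage) pair; by default only hits against
VLP-dataset contigs count (`crispr_vlp_only`), matching the network-figure
convention of the source analysis. Abundance summaries per VLP sample sum
phage species associated with anode-affiliated, cathode-affiliated,
non-electrode and no hosts; the categories may overlap and a multiply
associated phage counts in each.

## Electrode affiliation

For electrode E ∈ {anode, cathode}: a species passes when
`mean_E > 0.1%` and `mean_E > mean_NE` and `max_E > max_NE`, with NE the
union of tubing, suspension and inoculum samples — strict inequalities,
literal reading. The opposite electrode is not part of NE (the rule lists
only the three non-electrode compartments). A species passing for both
electrodes takes the one with the larger mean; an exact tie goes to the
anode (the source analysis reports disjoint sets without a tie rule, so one
had to be fixed). Abundances are percentages summing to ≤ 100 per sample,
with counts on contigs of unretained species reported as an unassigned
remainder.

## Hill-number dissimilarity

For a pair of samples with equal weights (w = 1/2), pooled frequencies
`p̄ = (p1+p2)/2`:

- `γ_q = (Σ p̄_i^q)^{1/(1−q)}`,
- `α_q = ½ (Σ_{ij} (p_ij/2)^q)^{1/(1−q)}` over nonzero entries,
- `β = γ/α ∈ [1, 2]`,
- `d = 1 − ((1/β)^{q−1} − (1/2)^{q−1}) / (1 − (1/2)^{q−1})` for q ≠ 1 and
  `d = ln β / ln 2` at q = 1 (exponential-Shannon limits).

This is the Chiu–Jost decomposition with the local overlap transform, whose
`1 − d` reads as the proportion of (order-q weighted) taxa two communities
share. Zero-abundance taxa are dropped before renormalization per pair
(Hill numbers are support-based); q within 1e-12 of 1 routes to the exact
limit branch, and the q → 1 limit is verified numerically in the tests.

PCoA Gower-centers `−d²/2` and eigendecomposes; only positive-eigenvalue
axes carry coordinates, negative eigenvalues are reported verbatim (no
Lingoes/Cailliez correction), and proportion explained is relative to the
positive part. Correlation between dissimilarity matrices uses Pearson r
over upper triangles with a two-sided Mantel permutation test
(`p = (1 + #{|r_perm| ≥ |r_obs|}) / (1 + n_perm)`): pairwise
dissimilarities are not independent, so a naive t-test would be
anticonservative; the source analysis does not name its test, so Mantel is
this package's documented choice. Constant matrices (e.g. q = 0 when every
taxon occurs everywhere) return `r = NA` rather than a spurious value.
Prevalence curves sort bins by completeness (ties by id) and chunk into
consecutive groups of 36, retaining and flagging a final partial group.

## The synthetic world

`generate_dataset()` emits a fully ground-truthed dataset shaped like the
study design it emulates: nine MECs sampled at anode, cathode, tubing and
suspension (inoculum and foam are off by default; no in-scope statistic
uses them), with one VLP sample per MEC. Defaults, fixed once:

| parameter | default | rationale |
|---|---|---|
| host species / phage species | 12 / 20 | desk scale; every stage still multi-cluster |
| genome size / contigs | 40–120 kb, 2–6 contigs, largest 40–60% | dominant-contig drafts; prophages always fit |
| phage size | 8–40 kb (contract bounds 5–161 kb) | typical tailed-phage range |
| mutation_rate | 0.005/bp | within-species ANI ≈ 99, margin ≫ 2 points to the 95% threshold |
| completeness | bins 55–100%, first bin of each species 75–100% | every species passes retention, so recovery tests measure the methods, not the filter |
| prophage / induction / crispr prob | 0.5 / 0.3 / 0.5 | roughly half of species carry each feature, as in mixed communities |
| spacers per array | 3–8, repeat 25–40 bp, spacer 28–40 bp | inside CRT's detectable ranges |
| protospacer_match_prob | 0.7 | most spacers traceable to a planted phage |
| affiliation_effect | 50× | strong electrode enrichment of electroactive taxa |
| ne_enrichment | 3× | non-affiliated species are bulk sludge organisms, modestly enriched off-electrode |
| abundance noise | log-normal, σ = 0.4 per sample (σ = 0.6 VLP), species scales log-normal σ = 1.5 | uneven community, reproducible location profiles |

Within-species bins differ only by block truncation (0.5–3 kb deletions,
each splitting a contig, down to the target completeness — so true ANI is
analytically known) plus point substitutions. Prophages are
mutation-perturbed insertions; CRISPR spacers destined to match are copied
verbatim from emitted VLP contigs; induced prophages are emitted verbatim
among the VLP. Background composition is i.i.d. uniform A/C/G/T, which
avoids spurious repeats that would confound CRISPR false-positive tests.
All randomness flows from one seed through named substreams, and emitted
files are byte-identical across runs.

**What a green test does and does not establish.** The generator does not
simulate sequencing error, assembly artifacts, strain mosaicism, horizontal
transfer, repeat-rich genomes, or compositional biases; real bins are
messier in all these ways. Green recovery tests establish that the
implemented logic is correct on data satisfying its assumptions — not that
the thresholds are optimal for any particular reactor.

Two ground-truth subtleties, both consequences of the stated world rather
than test conveniences:

- *Observability.* Truncation legitimately deletes planted prophages and
  arrays (that is exactly what the prevalence-vs-completeness analysis
  measures), so edge-recovery is scored against links whose signal survived
  in at least one bin (array intact; prophage fragment ≥ 5 kb).
- *Induction ambiguity.* At 95%-ANI species resolution, a prophage whose
  phage species is also free-living among the VLP is indistinguishable from
  an induced copy — the "also detected among the VLP" criterion shares this
  ambiguity. Induction recovery is therefore scored against prophage pairs
  whose phage species has any VLP contig, while `gt_induced.tsv` records
  the literally emitted induced copies.

## Degenerate inputs and error policy

Contract violations raise classed conditions: `too-short` (sequence < k),
`incompatible-sketches`, `infeasible-config` (e.g. no phage fits the
largest host contig), `invalid-config`, `empty-sample` (zero count
columns), `dangling-reference` and `duplicate-id` (cross-validation of
inputs, listing offenders), `missing-column`, `insufficient-samples`
(Mantel with < 4 samples), and `invalid-input`. Short contigs yield empty
CRISPR results rather than errors; empty spacer tables and edge lists keep
their schemas.

## Known limitations

- Nucleotide-space spacer matching misses diverged protospacers that
  translated-space search would find.
- Sketch ANI degrades on very incomplete bins (see clustering caveat).
- Prophage calling requires the phage to be present in the supplied phage
  set; novel prophages with no VLP or annotated counterpart are invisible.
- The Mantel permutation count bounds the smallest attainable p-value at
  `1/(1 + n_perm)`.
- Hill diversity here is taxonomic only; phylogenetic and functional
  variants are out of scope.
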