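---
title: "Bootstrap confidence for tumor clone inference: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bootstrap confidence for tumor clone inference: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloneboot)
```

## The problem

Bulk sequencing of a tumor sample aggregates reads from many cells. At each
somatic single-nucleotide variant (SNV) it yields a pair of counts — reads
carrying the variant and reads that do not — whose ratio, the variant allele
frequency (VAF), reflects how common the variant is among the sampled cells.
Deconvolution methods turn multi-sample VAF patterns into *clones* (binary
SNV presence/absence genotypes) and per-sample clone frequencies, which in
turn drive downstream inferences such as metastatic cell-migration
histories. All of these are point estimates built from noisy counts: a VAF
computed from 20 reads is far less stable than one computed from 1,000.
`cloneboot` quantifies that uncertainty by resampling the reads themselves.

## Read-level bootstrap

At every (sample, SNV) cell the observed reads form a two-class pool of
size $n = \mathrm{ref} + \mathrm{alt}$. A bootstrap replicate redraws $n$
reads from this pool with replacement; because there are only two classes,
the resampled variant count is exactly

$$\mathrm{alt}' \sim \mathrm{Binomial}\!\left(n,\ \frac{\mathrm{alt}}{n}\right),$$

and totals are conserved cell-by-cell. We implement the draw in this closed
binomial form rather than by materialising read lists; the two are
mathematically identical and the binomial form is $O(1)$ per cell. Each
replicate resamples every cell of every sample independently and the
per-sample replicates are bundled into one pseudo-multi-tumor dataset per
replicate index. Thirty replicates are the default; replicate $r$ draws its
seed deterministically from the master seed so any replicate can be
reproduced in isolation.

## The clone-deconvolution engine

The engine (`run_clonefinder_plus()`) is deterministic given its input and
consumes no random numbers, so all run-to-run variation comes from the
bootstrap itself.

**VAF clustering.** Per sample, SNVs with at least one variant read are
clustered by a one-dimensional binomial mixture over their (alt, total)
counts, fitted by EM with deterministic quantile initialisation; the
component count over $1..k_{max}$ (default 8) is chosen by BIC. Tumor
purity is not required. Clusters are ordered by descending fitted VAF and
linked into a chain with one level of sibling branching via the pigeonhole
rule on cancer cell fractions (CCF = 2·VAF): walking down the order, a
cluster becomes a sibling of the current tip when its CCF and its siblings'
CCFs still fit inside their common parent's CCF (slack 0.05), otherwise a
descendant. Equal-VAF ties order by smallest member SNV id. Candidate clones
accumulate SNVs from the root cluster to each target cluster.

**Pooling and filtering.** Candidates from all samples are pooled and exact
duplicates removed. Quality is assessed only on SNVs with at least 50
reference reads and 2 variant reads in some sample; candidates that no
QC-passing SNV distinguishes from another candidate are collapsed, and
candidates carrying no QC-passing SNV are dropped. (We read the
one-supporting-SNV rule this way because a literal "SNV unique to the
clone" requirement would delete every ancestral genotype whose SNVs are all
inherited by its descendants.)

**Phylogeny and missing clones.** A clone tree is built by neighbor joining
on Hamming distances with an appended all-zero germline genotype as the
outgroup; rows are sorted canonically first so the topology is independent
of input order. Ancestral genotypes are reconstructed by Fitch parsimony
with the root fixed to the germline state and ties resolved toward the
parent's state — with an all-absent root this favours absence, i.e. the
later gain; unseen ancestral genotypes join the candidate pool.

**Frequencies.** For each sample the clone frequencies solve

$$\tfrac{1}{2}\, f\, M = V, \qquad f \ge 0, \quad \textstyle\sum_j f_j \le 1,$$

by nonnegative least squares with an explicit zero-genotype normal-cell
component absorbing the remainder; the sum constraint is a heavily weighted
equality row. The relationship assumes diploid, copy-number-neutral
variants; inputs affected by copy-number alteration should either be
excluded or pre-scaled by supplying per-SNV cancer cell fractions
(`apply_ccf()`), in which case CCF/2 replaces the VAF. The active-set
solver uses SVD pseudoinverse inner solves so the rank-deficient systems
produced by near-duplicate candidate genotypes return the minimum-norm
minimiser instead of failing; iteration counts are bounded and the best
iterate is returned at the bound, keeping the pipeline total.

**Pruning, hybrids, finalisation.** Frequencies strictly below 1% mark a
clone absent from that sample; clones absent everywhere are removed and
frequencies re-estimated. SNV groups sharing a carrier-clone set (hence an
identical expected-VAF profile) are split in two by their observed-VAF
residual profiles across samples, using a deterministic 2-means whose
centres initialise at the farthest pair; the resulting group-A-only and
group-B-only alternates of every carrier clone are kept when they earn at
least the prune frequency somewhere. The ancestral + hybrid search repeats
to a fixpoint with an iteration cap of 10 (the search is not guaranteed
finite in general; in practice 2–3 iterations suffice). Finally, SNVs
assigned to no clone are attached to the clone whose expected-VAF profile
(half its frequency vector) is nearest in least squares, ties going to the
higher mean frequency.

## Consensus clones

Clones from all replicates are pooled; distinct genotypes are ranked by
occurrence count (ties lexicographic) and serve as group seeds in that
order. A clone joins the first group whose seed is within the grouping
cutoff (default 1 SNV difference) *and* whose seed genotype occurs at least
as often as its own: noise variants are absorbed into a stable clone's
group, but two clones that are each stable across replicates are never
merged — this keeps the guarantee that unanimous replicates reproduce the
point estimate exactly. Group support is the percentage of replicates
contributing at least one member. For the consensus sequence each replicate
votes once, through the member nearest the seed; a position is called 1 (or
0) when strictly more than 90% of votes agree, and ambiguous otherwise.
The 0-call uses the same threshold symmetrically. Note 9/10 = 0.90 is *not*
greater than 0.90: such positions are ambiguous.

## Migration histories

Given a clone phylogeny, the sites each clone occupies (frequency > 5%),
and the primary site, a minimum-migration site labeling is computed by
Sankoff dynamic programming with unit cost and the root fixed to the
primary site. A clone occupying $k$ sites acts as $k$ co-located copies:
its node pays $k-1$ when labelled with an occupied site, and it emits one
co-location path per occupied site other than its label (these carry zero
mutations — the same genotype observed in two sites). Traceback ties prefer
the parent's label at internal nodes, which favours fewer distinct sources;
at clone tips the choice is restricted to the clone's own sites whenever
one attains the minimum, so that a migration attaches to the branch leading
to the migrating clone and inherits that branch's mutations — without this
restriction a cost-equal labeling can express the same move as a
zero-mutation co-location, divorcing migrations from the mutations acquired
en route. Branch mutation counts come from the Fitch reconstruction
(gains only; losses contradict the gain-only model and are logged).

Per-replicate histories are pooled; a path's support is the percentage of
replicates containing it. The consensus keeps all paths at or above the
support threshold (default 60%) as solid, then adds the best-supported
remaining paths as tentative only while some observed site is unreachable
from the primary. Driver-mutation comparisons aggregate per replicate the
mean driver count and the mean driver rate (drivers/mutations, zero-mutation
paths excluded) for primary-sourced versus metastasis-sourced paths, and
compare the two classes with Welch's t-test; zero-variance degeneracies are
reported as t = 0 (identical means) or infinite t with a warning.

## The simulator

`simulate_truth()` emulates multi-tumor metastatic progression: a clone
tree grows by uniform attachment; each clone's incoming branch receives at
least one of the `n_snvs` SNVs (remainder multinomial), so genotypes obey a
perfect phylogeny; each metastatic site is founded by one (monoclonal) or
two (polyclonal) clone lineages whose parent's site is the migration
source, and subtrees inherit their founder's site; within a site, resident
clone frequencies are symmetric-Dirichlet distributed and sum to one.
`simulate_reads()` draws per-cell depths from a negative binomial (mean
100, dispersion 5 by default — depths mostly 30–250, matching the spread
seen in exome data; a uniform-range alternative reproduces wider empirical
ranges such as 8–1,436) and variant counts binomially at half the summed
frequency of carrier clones, times purity (default 1).

What the simulator does *not* model: copy-number alteration, sequencing
error, spatial growth within a tumor, clone sharing across sites other than
through seeding, or mutation loss. Passing tests therefore demonstrate
correct behaviour under the diploid, CNA-free, gain-only model the engine
itself assumes — not robustness to the violations of that model found in
real tumors. Driver flags are Bernoulli per SNV (rate 0.05, enriched
fourfold on founder branches) so driver-rate analyses have a known ground
truth.

## Benchmark and problem sizes

`run_benchmark()` is the package's evaluation harness: by default 10
simulated datasets with 5 tumor samples, 8–12 clones, 30–60 SNVs, depth
mean 100, and 30 bootstrap replicates each — sizes chosen so a full run
completes in a few minutes on a single core while spanning the clone and
SNV ranges above. It scores each consensus clone's genotype error (GE;
Hamming distance to the nearest true clone over sequence length, ambiguous
positions costing one half — half-credit is the neutral choice, and a flag
gives strict scoring) against its bootstrap support, and each pooled
migration path's support against its true/false-positive status. On these
conditions high-support (>50%) consensus clones have median GE 0, most
consensus clones have low (≤10%) support, and true paths carry far higher
median support than false ones — the qualitative signature that motivates
reporting bootstrap support with every clone in the first place.

```{r benchmark-example, eval = FALSE}
bench <- run_benchmark(n_datasets = 10, seed = 1)
bench
```

## Numerical choices and degenerate inputs

* Zero-coverage cells get VAF 0 with a warning (a bootstrap replicate can
  legitimately lose all variant reads at a position); zero-total SNV rows
  are dropped at read time.
* All-zero VAF samples yield an empty cluster chain with a warning; an
  all-candidates-filtered pool falls back to the single clone carrying
  every SNV.
* Pruning everything keeps the single highest-frequency clone with a
  warning.
* Clone-assignment ties in finalisation use a 1e-12 slack so algebraically
  equal squared distances compare equal in floating point.
* The genotype encoding for FASTA output is 0 → A, 1 → T, ambiguous → N,
  chosen for interoperability with tree software.

## Known limitations

Copy-number-altered variants violate the half-frequency relationship unless
pre-scaled by CCF. The VAF-clustering stage fits chains with a single level
of sibling branching; deeper branching within one sample is recovered later
by the ancestral/hybrid search rather than by the clustering itself.
Consensus supports attach to genotypes, not frequencies. Migration
inference assumes the primary site is known and sites are sampled; unit
migration costs do not model seeding-rate differences between sites.
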