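---
title: "Methods: windowed CNV calling and synteny anchoring in goatcnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed CNV calling and synteny anchoring in goatcnv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

goatcnv implements a read-depth copy-number-variation (CNV) pipeline for
contrasting wild and domestic goat cohorts, and a synteny-based scaffold
anchoring workflow for placing a fragmented assembly onto the chromosomes
of a related reference. Everything runs on either real inputs (BAM/SAM,
per-base depth tables, GFF3/BED annotation, PAF-like alignment hits, Ct
tables) or on synthetic cohorts produced by the package's own generators,
which carry known truth and make every stage testable offline.

# The depth model

Read depth is summarized in fixed sliding windows: 200 bp windows every
100 bp by default, so each interior base is covered by two windows and a
sequence of length $L$ carries $\lfloor (L - 200)/100 \rfloor + 1$
windows. From alignments, a read is assigned to every window containing
its leftmost aligned base; unmapped, secondary and duplicate-flagged
reads are excluded, and a mapping-quality floor can be applied. Leftmost
assignment is the cheapest deterministic convention; midpoint assignment
is available as an option and changes nothing for the downstream rules,
which only consume window counts. Inputs are assumed de-duplicated
upstream; only flag-based filtering is applied here. From a per-base
depth table the window value is instead the mean per-base depth over the
window; both conventions are supported because archived depth tracks are
often all that is left of an alignment.

Per sample, the **one-fold genome depth** is the unweighted mean window
count over all windows — the depth of the baseline diploid state. The
**CNV ratio** of a window is its count divided by this one-fold depth:
$\approx 1$ at two copies, $\approx 2$ at four, 0 in a homozygous
deletion. Per-chromosome means and population standard deviations are
kept separately because the gain rule below is a per-chromosome test.
Population rather than sample SD is used; at genome-scale window counts
the difference is far below every threshold in the pipeline.

# CNV calling rules

**Gains.** A window is elevated when its count exceeds its chromosome's
mean plus `sd_mult` (default 2) standard deviations. A frame of 7
consecutive windows qualifies when at least 5 of them are elevated
("five of seven"); a gain region is the union of elevated windows
covered by any qualifying frame, with overlapping or adjacent qualifying
frames merged and the region trimmed to its outermost elevated window.
We read "five out of seven *or more* sequential windows" as a sliding
7-window frame whose qualifying overlaps merge — a monotone and testable
interpretation; `k` and `frame` stay configurable. Trimming to the
outermost elevated window (rather than frame bounds) avoids padding
regions with sub-threshold windows. On a degenerate chromosome with zero
SD the threshold collapses to the mean and any window strictly above it
counts as elevated.

**Losses.** A window is a loss window for sample $s$ when its count
falls below $0.1\times$ that sample's one-fold genome depth *and* at
least one other sample has a count above $0.5\times$ its own one-fold
depth there. The cross-sample condition removes regions that are simply
unmappable in every sample. Loss windows then pass through the same
5-of-7 scan. The asymmetry between the gain rule (per-chromosome
mean + 2 SD) and the loss rule (genome-wide fractions) is deliberate and
mirrors how the two rules are stated in the CNV literature this package
follows. Loss calling refuses single-sample input, where the
cross-sample condition is undefined.

Whether gain calling should also impose a cross-sample condition is an
open question; none is imposed, matching the rule as stated. Nearby
same-type regions can be merged with `merge_regions()` (default gap: one
step); merging is done after region definition. For genome-wide maps,
`aggregate_region_counts()` bins regions strictly longer than 800 bp
into 1-Mb non-overlapping bins by region start.

# Candidate genes

The per-gene CNV ratio is the **median** ratio over windows overlapping
the gene span (configurable to the mean). The aggregation statistic is
not prescribed anywhere we could follow, so the median was chosen: it
ignores the diluted boundary windows at CNV breakpoints. A gene is a
**candidate deletion in domestic goats** when it overlaps a called CNV
region and its ratio is below 0.2 in *all* domestic samples while at
least 0.5 in *all* wild samples. **Candidate duplications** mirror this:
at least `dup_high` (default 1.5) in all domestic samples and below
`dup_wild_max` (default 1.5) in all wild samples. The duplication
thresholds are this package's own defaults for "single copy in one
cohort, multi-copy in the other" — no printed rule exists for them —
and are prominently configurable. Whether the gene ratio should be
restricted to the overlapping CNV region is likewise open;
`require_cnv_overlap` restricts deletions and can be disabled.

External presence/absence evidence (e.g. a tabulated protein search
against the counterpart assembly) can be attached to calls; running any
similarity search is out of scope. With `require_external = TRUE`,
deletion verdicts without supporting "absent" evidence are downgraded.

qPCR corroboration uses standard $\Delta\Delta C_t$: per sample, the
target's mean Ct is normalized to a single-copy reference gene
(C7orf28b by convention), then to a calibrator sample assumed to carry
2 copies (a diploid single-copy locus); relative copy number is
$2 \times 2^{-\Delta\Delta C_t}$. The calibrator copy number is a
parameter because the normalization convention only fixes ratios, not
absolute copies.

# Scaffold anchoring

Alignment hits (PAF or 8-column tabular) between scaffolds and reference
chromosomes are clustered per (scaffold, chromosome): successive hits
join a chain while the gap between their target starts is at most
100 kb. An **orphan** — a single-hit chain shorter than 500 bp — is
discarded; the orphan notion is not defined in the source pipelines this
emulates, so both the single-hit reading and the 500 bp floor are
configurable decisions of this package. A scaffold is **placed** when
its longest chain (by *total aligned length*, the sum of member hit
lengths — robust to sparse chains, unlike the chain span) is more than
twice the second longest; exactly twice is ambiguous, and ambiguous
scaffolds stay unanchored. A chain's strand is the length-weighted
majority of its members.

Placed scaffolds are concatenated per chromosome in order of chain
start, reverse-complemented when "−", and separated by 100 N's — the
gap size between anchored scaffolds is unknowable from alignments, so
AGP v2.1 gap rows use type `U` (unknown size) with linkage evidence
`align_genus`. The AGP exactly describes the emitted FASTA;
`assemble_from_agp()` reverses it and is byte-identical by construction
(and by test).

The Y-chromosome variant replaces plain 100-kb clustering with
repeat-aware gap rules: hits merge when the gap between them is under
1 kb, or when it is between 1 kb and 5 kb and *more than* 50% of the gap
is repeat sequence (strict at both boundaries). Protein hits supporting
Y scaffolds are pre-filtered at 60% protein coverage (strictly below is
dropped); the protein alignment step itself is reduced to its filterable
artifact — a coverage table — because running the aligner is out of
scope. Ordered placements follow the reference contig order and offset,
and the same AGP/FASTA emission builds the draft Y.

# The synthetic cohorts

The generators produce every input the pipeline consumes, with truth
attached. Depth is simulated **directly at window level**: window counts
are drawn from Poisson (default) or negative binomial
($\mathrm{var} = \mu + \phi\mu^2$) with mean
$\lambda \cdot c/2$ for copy number $c$, $\lambda = 30$ reads/window by
default — the ballpark of 6–8× short-read resequencing summarized in
200-bp windows. Windows partially overlapping an event take a
length-weighted mean copy number, which makes truth well-defined at
breakpoints. Read-level simulation (FASTQ, error models, GC bias) is a
non-goal: the caller consumes only window counts, and window-level
simulation is orders of magnitude faster. A thin writer can spread
window counts into a per-base depth TSV to exercise that reader, with
the caveat that overlapping windows make the spread non-invertible.

Fragmented assemblies are made by partitioning reference sequences at
random breakpoints (minimum scaffold length enforced), flipping a random
subset, and emitting one co-linear hit chain per scaffold plus short
(100–400 bp) spurious hits at a Bernoulli rate per true hit. Spurious
hits are deliberately shorter than half of any true chain so that the
dominance rule's behaviour under noise can be tested as a property.
qPCR tables follow
$C_t = C_0 - \log_E(\text{copies}) + \mathcal{N}(0, \sigma)$ with
efficiency $E \in (1, 2]$.

What the generators do *not* emulate: mappability structure, GC bias,
repeat-driven multi-mapping pile-ups, library-size differences between
samples, dispersed segmental duplications, or alignment breakpoint
noise. Passing tests therefore demonstrate that the rules are
implemented exactly and behave correctly under clean count noise — not
that the thresholds are well-calibrated for any particular real dataset.

# Numerical and design notes

* Coordinates are 0-based half-open internally; per-base TSV is 1-based;
  BED/bedGraph/AGP follow their own conventions on output.
* Trailing sequence shorter than one window is never windowed; sequences
  with fewer than 7 windows are flagged unusable and skipped by the
  detectors with a warning.
* All generators are seeded and byte-identical under a fixed seed.
* Region `mean_ratio` is the mean count over the region divided by the
  one-fold depth; merged regions combine it length-weighted.
* Problem sizes used in the shipped property checks — 50,000-window
  genomes for sensitivity/specificity and ratio calibration, 50
  simulated cohorts for candidate-gene recovery, 20-scaffold assemblies
  for anchoring — were chosen as the smallest sizes at which the
  binomial/CLT bounds in those checks are comfortably discriminating.

# Known limitations

* The five-of-seven reading ("any 7-frame with ≥5 qualifying windows",
  merged) is one of several defensible parses of the rule's phrasing;
  it is monotone in the thresholds and is asserted against brute-force
  enumeration, but other parses would shift region boundaries slightly.
* Gain thresholds react to the per-chromosome SD, so a chromosome dense
  in true gains has an inflated threshold and reduced sensitivity —
  inherent to the rule, not corrected here.
* The duplication rule and the orphan filter are documented package
  defaults, not reproductions of a printed rule.
* A placement's position is its chain's target start. A spurious hit
  that falls within the clustering window of a true chain merges into
  it and can pull the reported position by up to that window
  (chromosome and orientation are unaffected), so under hit noise two
  closely spaced scaffolds can swap in pseudo-chromosome order.
* No GC correction, mappability masking or joint segmentation (HMM/CBS)
  is performed; these are non-goals.

# A worked example

```{r, eval = FALSE}
library(goatcnv)

cfg <- sim_config(seed = 7, sequence_length = 1e6,
                  mean_read_count_per_window = 30)
ref <- simulate_reference(cfg, n_genes = 20, gene_length = 1500)
genes <- ref$genes

events <- gene_events(genes, genes$gene_id[c(2, 9)], c(0L, 4L),
                      seqlengths = ref$sequences)
cohort <- c(lapply(paste0("dom", 1:4), copy_number_landscape,
                   events = events),
            lapply(paste0("wild", 1:2), copy_number_landscape))
sim <- simulate_depth_tracks(ref, cohort, cfg)

summaries <- lapply(sim$tracks, summarize_depth)
profiles  <- Map(cnv_ratio, sim$tracks, summaries)
regions   <- do.call(rbind, c(
  unname(Map(detect_gain_regions, sim$tracks, summaries)),
  unname(detect_loss_regions(sim$tracks, summaries))))

labels <- c(setNames(rep("domestic", 4), paste0("dom", 1:4)),
            setNames(rep("wild", 2), paste0("wild", 1:2)))
classify_candidates(genes, profiles, labels, regions = regions)
```
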