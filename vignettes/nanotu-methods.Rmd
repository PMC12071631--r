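---
title: "Methods: OTU clustering and consensus assembly for nanopore amplicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OTU clustering and consensus assembly for nanopore amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Oxford Nanopore amplicon sequencing reads whole marker genes — full-length
16S rRNA, complete fungal ITS regions — in single reads, but at per-base
error rates (5–10%, dominated by indels in homopolymer tracts) that defeat
the exact-sequence-variant methods built for short reads. `nanotu` groups
such reads into operational taxonomic units (OTUs) *de novo*, without a
reference database, and assembles one consensus sequence per OTU whose
accuracy far exceeds any single read. Because neither the clustering nor
the consensus step assumes a minimum read length, amplicons of any length
are usable — including ITS regions of a few hundred bp that assembly-based
pipelines cannot process.

## Pipeline model

### Read preparation

Reads must arrive demultiplexed and barcode-trimmed; `nanotu` deliberately
does not attempt barcode auto-detection (which misfires on amplicon data)
and warns when primers sit suspiciously far (> 30 bp) from read ends.
Each read must contain the forward primer at one end and the reverse
complement of the reverse primer at the other, located by IUPAC-aware
approximate matching (mismatches plus indels up to a fraction
`primer_error_rate`, default 0.1, of the primer length — the tolerance
conventional primer trimmers default to). Reads matching on the minus
strand are reverse-complemented, so all surviving reads share one
orientation; reads lacking either primer are removed. Surviving reads are
filtered on:

* **median quality** ≥ `q_min` (default Q20, inclusive). Basecallers pin
  saturated probabilities to Q90 (a float16 artifact); such positions
  carry no information and are excluded from the median. If every
  position of a read is capped, the full-vector median is used — such
  reads are pathological and vanishingly rare.
* **length** within the expected amplicon bounds (`amplicon_presets`
  ships the standard windows: 350–600 bp for 16S V3–V4, 900–1600 for
  V1–V9, 100–500 for ITS1/ITS2, 300–1200 for the full ITS region).

Every rejection is counted once in an attrition log whose reasons sum to
the input read count, making read loss auditable per sample.

### Feature collection

Each read is homopolymer-compressed (`...XYYYYXXY... → ...XYX...`) —
run-length information is where nanopore errs most, and retaining it
splits reads of one template across clusters. The compressed read's k-mer
signature (counts of all `4^k` words, default `k = 6`; windows containing
N are skipped, not imputed) forms a row of an `N × 4^k` matrix.
Signatures are compositional — totals reflect read length, not abundance
— so each row is centred-log-ratio transformed,
`ln((x + 1) / g(x + 1))`, with a +1 pseudocount keeping the zero-heavy
4096-dimensional rows finite. Raw counts versus frequencies is immaterial
here: CLR removes per-row constants. Reverse-complement k-mer collapsing
is *not* applied, because reads are already plus-oriented and collapsing
would discard signal. Compressed sequences are used only here, never for
consensus.

### Clustering

The CLR matrix is reduced by PCA to 30 components (noise suppression and
speed; the component count is capped by the rank bound `min(30, N, 4^k)`),
then embedded to 2-D by seeded, single-threaded UMAP
(`n_neighbors = 15`, `min_dist = 0.1`, the library defaults), and
clustered by HDBSCAN with Euclidean distance. Reads in low-density
regions get the noise label (−1) and are excluded from consensus and
abundance. UMAP and HDBSCAN run in a bundled Python worker
(`umap-learn`, `scikit-learn`); with a fixed seed the whole chain is
deterministic, and R-side guards handle the degenerate cases (fewer than
4 reads; byte-identical feature rows, which arise from error-free
duplicate reads and make a neighbourhood graph meaningless).

HDBSCAN settings that departed from library defaults, chosen for the
geometry UMAP produces here:

* `min_cluster_size`: `max(5, ⌈0.001·N⌉)` unless set explicitly.
* `min_samples = 5`, decoupled from `min_cluster_size`;
  `cluster_selection_epsilon = 0.5` embedding units;
  `allow_single_cluster = TRUE`. A sample containing a *single* amplicon
  variant embeds as one diffuse cloud with no density contrast, which the
  conservative library defaults label entirely as noise. These settings
  recover the lone cluster in that case while leaving well-separated
  multi-variant embeddings unchanged (verified on identical inputs).

Before alignment each cluster is pruned: reads outside mean length ± 10 bp
or outside mean GC ± 2 population standard deviations are dropped
(outliers here are usually chimeras, barcode remnants or mis-clustered
reads). Clusters are renumbered by decreasing size, ties by original
label, for stable output.

### Consensus

Selected reads (their original, uncompressed sequences) are multiply
aligned with MAFFT (default parameters); if MAFFT is absent an internal
center-star aligner satisfying the same contract (degapping any row
reproduces its read; qualities carried to aligned coordinates) takes
over with a warning. Per alignment column:

1. if the gap is *strictly* the most common symbol → `-`. A gap/letter
   tie goes to the letter: deletions are nanopore's dominant error mode,
   so the rule is biased against over-deletion.
2. otherwise, among letters supported by ≥ `min_support` reads
   (default 3), the letter with the highest *summed* Phred quality is
   the candidate (ties: higher count, then A < C < G < T);
3. the candidate is emitted only if it also has (tied-)top frequency;
   a frequency/quality conflict means the column is genuinely ambiguous
   → `N`;
4. no letter with sufficient support → `N`.

Two numerical choices deserve note. First, the letter comparison uses
summed quality (quality-weighted support), not the per-letter mean: a
mean over 3 reads is sampling noise against a mean over 90, and under the
mean reading a handful of misaligned high-quality bases flags 5–10% of
well-supported columns as ambiguous, capping consensus identity near 90%
— inconsistent with what positional consensus achieves on this data. The
summed vote overturns the frequency winner only when counts are close
and quality evidence is decisive; all rule branches above, including the
conflict-to-N branch, behave identically on the canonical small cases.
Second, Phred values at the Q90 cap contribute zero weight, for the same
reason they are excluded from the median read quality.

Gaps are then stripped, terminal poly-N runs trimmed (on by default;
interior Ns are kept), and — optionally, when the external `medaka`
binary is present — the consensus is polished; polishing failures
degrade gracefully to the unpolished sequence. The OTU's abundance is
its cluster's read count.

### Single and pool modes

*Single* mode processes each sample independently. *Pool* mode builds one
feature matrix over all samples, clusters jointly, assembles one
consensus per pooled cluster and then restores per-sample composition by
counting each sample's reads per cluster. Pooling is the right choice for
shallow samples and long amplicons: a community member at 2% of a sample
may leave too few reads to form a per-sample cluster yet be abundant
across samples. Reads the joint clustering marks as noise are excluded
from composition restoration (they belong to no OTU by construction).
Relative abundances are computed over each sample's clustered (non-noise)
reads; noise counts remain visible in the attrition log. On one sample,
pool and single mode give identical results at the same seed.

### Taxonomy

OTU taxonomy uses external `blastn` output (tabular format with query
coverage). Hits must meet *both* a coverage and an identity threshold;
among qualifying hits the highest bitscore wins, ties broken by e-value
and then subject id for order-independence. Two presets reflect common
practice: `lenient` (coverage ≥ 60%, identity ≥ 95%) for transparent
mock-community work, `strict` (coverage ≥ 98%, identity ≥ 97%) to
suppress noise in complex communities. Queries with no qualifying hit are
`Unclassified`. Purpose-built classifiers (IDTAXA, MAPSeq, QIIME,
SPINGO) remain the recommendation for serious taxonomic work.

## The simulator

`community_spec()`/`simulate_dataset()` generate multi-sample FASTQ with
per-read ground truth (template of origin and realized edit counts,
recorded in the read id and `truth.tsv`). A read is
`primer_f + template + revcomp(primer_r)` (degenerate primer positions
instantiated randomly per read), mutated by per-base substitution,
insertion and deletion (defaults 0.03/0.02/0.03 ≈ 8% total, the
Guppy-era regime), with indel rates multiplied (default 2×) inside
homopolymer runs of length ≥ 3. Qualities for correct bases come from
N(25, 6); erroneous bases *and bases flanking a deletion* draw from
N(12, 4) — basecaller confidence dips where it errs, and the
quality-weighted consensus rule is designed around exactly that
correlation, so a simulator violating it would model a different
instrument. A configurable fraction of positions (default 1%) is pinned
to Q90, reproducing the cap artifact. Reads flip strand with probability
0.5. Template assignment per sample is multinomial in the community
proportions; a fixed seed makes the dataset byte-reproducible.

What the simulator does *not* emulate: chimeras, barcode/adapter
remnants, length-dependent amplification bias, context-specific (rather
than run-length-specific) error hotspots, and quality strings estimated
by a real basecaller. Passing tests therefore demonstrate the algorithm's
correctness under the stated error model, not end-to-end performance on
any particular flow cell.

## Validation design and problem sizes

The test suite validates each stage against independent oracles
(enumeration for k-mer counting, hand-computed CLR values, constructed
alignments for every consensus branch) plus property checks (attrition
conservation, compression idempotence, CLR zero-sum, strand symmetry,
permutation invariance, seed determinism). End-to-end checks simulate:
identical error-free reads (byte-exact consensus); 100 and 200 reads at
8% error from a 500-bp template (unpolished consensus identity ≥ 99% /
≥ 99.5%); three templates at 0.5/0.3/0.2 with 600 reads at 5% error, for
both 450-bp and 300-bp amplicons (exactly 3 OTUs, ≥ 95% cluster purity,
abundance error ≤ 0.05 against the realized composition); a 2% minor
taxon across 5 × 300-read samples detected in pool mode only; and
single/pool agreement on a lone sample. Abundance recovery is judged
against the *realized* multinomial composition of the simulated sample
rather than the nominal proportions — the former is what the sample
contains, and the difference between them is generator sampling noise,
not pipeline error. These problem sizes keep any single simulation under
a few minutes on one CPU while leaving clustering statistically
non-trivial.

## Known limitations

* Cluster resolution is bounded by the k-mer signature: templates above
  ~97% identity can merge into one OTU (a general property of
  signature-based clustering at k = 6).
* No chimera detection.
* Consensus accuracy degrades below ~10–15 supporting reads; clusters
  under `min_support` are skipped outright.
* The UMAP/HDBSCAN stage requires the bundled Python worker's
  dependencies (`umap-learn`, `scikit-learn`) on the host.
* Determinism is guaranteed per machine/library version; UMAP embeddings
  may differ across library versions (cluster *content* is robust in our
  experience, coordinates are not).
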