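---
title: "Models and methods behind thermosplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind thermosplice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`thermosplice` analyses how a shift in ambient temperature (16 °C to 25 °C
in the motivating design) changes alternative splicing, and how that change
relates to the gene-body histone mark H3K36me3. This vignette documents the
statistical models, the tunable parameters, the synthetic-data generator,
and the design decisions taken where several defensible choices existed.

## Event model

All coordinates are 0-based half-open internally; GTF converts at the
boundary, BED/bedGraph pass through verbatim. Events are found by comparing
every unordered pair of a gene's transcript exon chains and matching five
local patterns, each anchored in shared exon sequence on both sides:

* **IR** — one chain has an intron lying strictly inside a single exon of
  the other chain.
* **ES** — one chain carries an internal exon; the other joins the two
  flanking exons with a junction at exactly the facing boundaries.
* **A5 / A3** — the chains share one intron boundary and differ at the
  other; which side is the donor (5′) is decided by strand.
* **MXE** — each chain carries one of two non-overlapping internal exons
  between shared flanking boundaries.

Anything else (alternative first/last exons, multi-exon or nested
differences) is deliberately not an event. Pairwise comparison rather than
a global splice graph matches the enumerated-isoform setting the package
targets; duplicate discoveries across pairs are collapsed by an event key
(type, chromosome, strand, alternative region, inner anchor boundaries),
and event ids are the first 12 hex digits of an MD5 of that key, so they
are stable across runs and machines.

The *inclusion* form is always the form with more transcribed sequence in
the alternative region (retained intron, included exon, longer splice-site
variant; for MXE the upstream-in-transcript exon), and PSI is the inclusion
fraction. Anchors must share at least 1 bp of exon overlap; degenerate
anchors discard the candidate. A gene without strand information is
accepted with a warning but raises an error if an A5/A3 candidate is found,
because donor/acceptor assignment is then undefined.

One geometric note: flipping the strand at fixed coordinates swaps A5 and
A3 (the donor side moves to the other intron edge), whereas reflecting all
coordinates *and* flipping the strand preserves the transcripts' 5′→3′
geometry and therefore every event type. The test suite asserts both facts.

## PSI and the differential-splicing test

Isoform-specific read counting assigns a read to a form when all its blocks
nest in the form's exon segments and every junction it spans matches a form
junction exactly; reads compatible with both forms or neither are ignored.
With a Uniform(0,1) prior, `n_incl` inclusion- and `n_excl`
exclusion-specific reads give a `Beta(n_incl + 1, n_excl + 1)` posterior;
the reported PSI is its mean with a central 95% credible interval.

Differential splicing between conditions a and b is tested on *pooled*
replicate counts with a Savage–Dickey density ratio at ΔΨ = 0. Under
independent uniform priors the prior density of Δ = Ψ_b − Ψ_a at 0 is
exactly 1 (triangular on [−1, 1]), so BF₁₀ = 1 / p(Δ = 0 | data). The
posterior density at 0 is estimated from paired Beta posterior draws
(default 100,000, explicit seed) with a Gaussian kernel, bandwidth from
Silverman's rule floored at 0.01; the floor keeps the estimate stable when
the posterior is extremely concentrated. Reported Bayes factors are capped
at 10¹² so that saturated evidence stays finite in tables and JSON. The
test suite cross-checks the estimator against the exact overlap integral
∫ f_a(t) f_b(t) dt of the two Beta densities.

Individual replicates drive two filters:

* **Support** — at least `min_reads = 20` isoform-specific reads in at
  least `min_reps = 2` replicates of *each* condition. The alternative
  reading "in all replicates" is one configuration change away
  (`min_reps = n_replicates`).
* **Consistency** — the maximum within-condition spread of per-replicate
  posterior-mean PSIs (equivalently the maximum pairwise difference) must
  be *strictly* smaller than the absolute difference of the condition means
  of those per-replicate PSIs; ties fail. Replicates with zero
  isoform-specific reads carry no PSI information and are excluded from
  this computation, though they still count against the support threshold.
  Spread could also have been defined as a variance, and the
  between-condition difference on pooled rather than mean PSIs; the
  implemented choice is the most direct reading and is stated here rather
  than asserted as the only one.

An event is significant (DiS) when it passes both filters and BF ≥ 5.
No multiplicity correction is applied across events: the Bayes-factor
threshold itself is the decision rule, and the null calibration of the
whole cascade is verified by simulation (null significant fraction ≤ 5% at
the default design).

An event is **H3K36me3-dependent** when significant in the wild type but in
no methyltransferase mutant, **independent** when significant in every
genotype, and unclassified otherwise. Genotype-level effect-size shifts are
compared with a two-sample Kolmogorov–Smirnov test on |ΔΨ| (asymptotic
p values).

## Chromatin integration

Regions are associated with genes by **containment** in the gene span by
default — the literal reading of association within gene start and end —
with `overlap_mode = "any"` and `"midpoint"` available because containment
is strict for regions straddling gene boundaries. Metagene profiles use a
fixed ±2 kb window in 50-bp bins around TSS or TTS (no gene-body scaling);
minus-strand genes are reversed so positive offsets always point downstream
of transcription, and genes whose window leaves the track are skipped and
counted. Event-to-region distance is the minimum gap between the event's
alternative region and any region of its gene (0 when overlapping, missing
for unmarked genes); dependent-versus-independent distances are compared
with a one-sided Mann–Whitney test (exact for small untied samples,
continuity-corrected normal approximation otherwise) — no specific test
being canonical for this contrast, the choice is recorded in the output.
Region widths between temperatures use the two-sided counterpart. Replicate
track agreement is Pearson correlation of 1-kb-binned sums after dropping
bins above the 0.999 quantile of either track, which guards the correlation
against a handful of extreme-count regions.

## Expression, enrichment, phenotype

Differential expression is delegated to DESeq2 (negative-binomial Wald
test); the package applies the thresholds |log2FC| ≥ 1 and BH-adjusted
p < 0.05 on top, and genes filtered to `NA` adjusted p are never called.
A moderated test is genuinely necessary here, not a convenience: at three
replicates per condition an unmoderated per-gene test has essentially no
power after FDR correction because null genes with accidentally tiny
variance dominate the ranking. The package's own `size_factors()`
(median-of-ratios over genes positive in all samples) is retained as a
tested primitive and agrees exactly with DESeq2's estimator.

Term enrichment is the upper-tail hypergeometric probability P(X ≥ k) per
term with BH correction across tested terms; a term is reported when the
adjusted p is below 0.05 and at least five *study* genes hit it (k ≥ 5 —
the "at least five genes" filter could also mean five term members; the
study-hit reading is implemented and switchable via `min_genes`). No
ontology-graph propagation is performed; term maps are taken as given.

Flowering phenotypes are summarised per genotype as the mean over replicate
trays of (tray mean at 16 °C) / (tray mean at 25 °C), for days-to-bolting
and rosette leaf number; 1 means no temperature response, values above 1
mean accelerated flowering at the higher temperature. Plants are never
pooled across trays, matching the averaging order of the assay design.
Genotypes are compared with the pooled-variance Student's t-test on the
per-tray ratios — the ratio being the quantity of interest — rather than on
raw trait values per condition; with constant ratios in both groups the
degenerate t is reported as 0 (equal means) or ±∞.

## The synthetic-data generator

`sim_config()` encodes the study design the analysis assumes: 300 genes
(one event each, mixed over the five types, both strands, 50 genes per
chromosome with 2-kb gaps), three replicates per condition, ~100
isoform-specific reads per event and replicate (Poisson depth, Binomial
inclusion counts), half the events with a true |ΔΨ| of 0.3 (random sign,
baseline PSI uniform in 0.35–0.6 so shifted values stay well inside [0, 1]),
a wild type plus two mutants whose temperature shift is fully attenuated at
mark-dependent events, mark regions centred 500 bp downstream of the TSS
(clamped into the gene span so containment association is exact) with
widths 300 bp at 16 °C and 450 bp at 25 °C, occupancy tracks as Gaussian
bumps over the regions plus background noise in 10-bp bins, negative-
binomial expression counts (dispersion 0.1, 10% of non-DiS genes shifted by
|log2FC| = 2), and flowering trays of 15 plants with days-to-bolting
normal around genotype/condition means (wild type 70 → 50 days, mutants
70 → 69) rounded to the 2-day screening grid. Where the motivating design
states a value (replicates, tray sizes, screening interval, thresholds,
peak offset) the default *is* that value; remaining magnitudes (depths,
dispersion, baseline PSI range) were fixed once at values typical for
plant RNA-seq/ChIP-seq work.

Counts are generated at the event level rather than by placing reads; an
optional block-alignment emitter (`gen_read_alignments()`) exists to
exercise the read-counting rules. The generator therefore does **not**
emulate read-level artefacts — mappability and GC bias, positional bias,
ambiguous multi-gene reads, transcript-degradation (NMD) dynamics, overlap
of multiple events in one gene, or correlated replicate noise. Passing
recovery tests consequently demonstrates that the statistical machinery is
correct and calibrated under its own model, not that real libraries meet
that model.

Every generator takes its randomness from one base seed through fixed
per-stage offsets; identical configurations produce byte-identical output
files. `run_pipeline()` chains simulation → event enumeration →
per-genotype DiS → dependence classification → expression/overlap/
enrichment → chromatin integration → phenotype and writes a manifest with
seeds, input digests and row counts (the manifest's timestamp is the only
non-reproducible output). The test suite exercises the full chain at 300
genes with 100,000 posterior draws per Bayes factor and smaller designs
(40–1000 genes) for targeted checks; these sizes keep each recovery
property measurable with comfortable margins while the whole suite stays
quick to run.

## Numerical and degenerate-input conventions

* Bayes factor: kernel bandwidth floored at 0.01; posterior density floored
  at 10⁻¹² (hence the 10¹² BF cap); draws are seeded and the seed recorded.
* `estimate_psi(0, 0)` returns the prior: mean 0.5, interval (0.025, 0.975).
* Consistency filter: ties fail (strict inequality); empty replicate sets
  fail.
* Zero-depth replicates: counts (0, 0), excluded from consistency, fail
  support.
* Chromosome names are never normalised; disjoint chromosome namespaces
  between inputs warn rather than error.
* Unstranded genes: accepted with a warning, error only on A5/A3
  candidates.
* Distance comparison drops unmarked genes and reports how many were
  dropped; an empty side after dropping is an error.

## Known limitations

Complex and nested splicing differences are not decomposed; alternative
first/last exons are out of scope by design. The Bayes factor tests each
event marginally — no sharing of information across events and no FDR over
the BF decisions. Region association ignores strand. The KS p value is
asymptotic and the Mann–Whitney normal approximation is used whenever ties
are present. DESeq2 is used with its defaults apart from the stated
thresholds; no shrunken-LFC variant is applied.
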