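---
title: "Methods and design notes for inbredvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for inbredvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(inbredvar)
```

This vignette records the models, parameter choices and numerical
conventions behind `inbredvar`, and what the synthetic-data experiments do
and do not demonstrate about real resequencing panels.

# The setting

Elite inbred panels (soya bean and similar selfing crops) are expected to
be homozygous nearly everywhere. Whole-genome resequencing of such a panel
yields (i) a large nucleotide-variant catalogue whose quality is
controlled by hard site filters and checked against an independent
genotyping array, (ii) an LD landscape so strong that a modest subset of
tag SNPs carries most of the haplotype information, and (iii) a structural
variant (SV) catalogue assembled from several callers with complementary
detection strategies. A recurring artefact ties these threads together:
when a genomic segment is duplicated in an accession but collapsed in the
reference assembly, reads from both copies pile onto one locus and produce
dense clusters of heterozygous calls with elevated depth — in an inbred
line, clustered heterozygosity is a duplication signature, not genuine
residual heterozygosity.

# Site filters

`applySiteFilters()` retains a site iff all six conditions hold: at most
two alleles; both-strand read support for every called allele; QUAL >= 32;
MQ >= 20; depth >= 2; MAF >= 0.02. Two conventions are deliberate:

* The underlying rules are stated as removals under strict inequalities
  (e.g. "QUAL < 32 is removed"), so retention is inclusive at the
  thresholds. This boundary behaviour is tested explicitly.
* A record failing several rules is tallied once, under the first failing
  rule in the order above, so the tally decomposes the removals exactly.

The depth rule is interpreted as site-level mean depth. Whether a
read-depth minimum should instead mask individual genotypes is ambiguous
in this kind of protocol; a per-sample mode (`depth_mode = "sample"`,
which masks low-depth genotypes and recomputes MAF on the survivors) is
provided behind a flag and documented as an interpretation.

# Variant annotation

Contexts use the precedence splice_site > exonic > intronic >
up_downstream > intergenic, with splice sites defined as the canonical
first/last 2 bp of an intron (no wider splice-region window) and
up/downstream as strand-aware 5-kb flanks, pooled into a single class in
summaries. The impact classifier is intentionally compact: CDS indels are
frameshift when the length difference is not a multiple of 3; CDS
substitutions are classified by retranslating the spliced CDS with the
standard codon table (`no.init.codon = TRUE`, so a damaged ATG is
start_lost rather than silently re-initialized); splice-terminus variants
are donor/acceptor by strand. Variants hitting several genes are
classified per gene, and the most severe effect is the variant's summary
label. It is a simplified effect predictor — no UTR subclasses, regulatory
features or NMD logic — and the published impact-category percentages from
full annotation pipelines are not expected from it.

# Genotype concordance and the indel surrogate

`alignLoci()` intersects two genotype matrices on (chrom, pos), reconciles
ref/alt-swapped sites by flipping codes, and drops irreconcilable alleles
with a message. Comparisons are classed homozygous/heterozygous from the
first platform's call, or "indel" for length-polymorphic sites.
Arrays typically leave indel loci uncalled; with
`indel_surrogate = TRUE` a comparison where the array is missing but the
sequencing call is present is routed to the indel class and counted
concordant iff the sequencing call carries the alternative allele (the
variant "explains" the array dropout). The comparison rule for such pairs
is not standardized anywhere; this operationalization is ours and both
denominators (with and without surrogate routing) are available.

# The stand-in imputer

`imputeMissingSimple()` is a transparent k-nearest-haplotype voter, not a
reimplementation of a phased-haplotype model: for each missing genotype
the k = 5 panel samples with the smallest Hamming distance over the w = 50
nearest typed flanking sites (same chromosome) vote by majority, ties
breaking toward the panel major genotype. Panel samples that match the
target exactly over the window dominate the vote, which makes the
zero-distance guarantee exact: a target identical to a panel haplotype is
reproduced verbatim. k and w are package defaults, not published values.
The leave-one-out protocol (`evaluateUntypedImputation()`) removes one
accession from the panel per permutation, imputes its untyped loci from
its low-density genotypes, and reports per-permutation and mean accuracy
(fraction of imputed genotypes identical to the withheld truth; no dosage
metric). Permutations are drawn without replacement under a seed.

# LD, tag SNPs, saturation

With <1% genuine heterozygosity, each homozygous individual contributes
one observable haplotype, so haplotype frequencies are estimated directly
from jointly homozygous samples (heterozygous/missing genotypes excluded
pairwise) instead of running EM phasing. From the 2x2 haplotype table:
D = p_AB − p_A p_B, r² = D² / (p_A p_a p_B p_b), and
D′ = |D| / D_max with D_max = min(p_A p_b, p_a p_B) for D > 0, else
min(p_A p_B, p_a p_b).

Tag-SNP pruning works in 50-SNP sliding windows (step of one SNP — the
window semantics of the original tooling are version-dependent, so
slide-by-1 is our documented choice): sites in perfect LD (r² = 1 within
1e-9) are grouped by transitive closure restricted to the window, and the
left-most site of each group is the tag. LD decay is the midpoint of the
first distance bin whose mean r² drops below 0.2 with all later occupied
bins also below; if LD never decays in range the result is flagged
open-ended rather than extrapolated.

`saturationAnalysis()` uses nested subsets: each replicate draws one
random sample order and every size takes its prefix. Each subset is still
a uniform draw without replacement, and per-replicate curves are
non-decreasing by construction, so the replicate means (default 10) are
smooth accumulation curves rather than independent draws with crossing
noise.

# SV consensus construction

Raw-call filters: spanning pairs > 10, genotype quality > 30, breakpoints
clear of padded centromeres (±1 kb) and assembly gaps (±50 bp). The
read-depth ratio (mean carrier depth over mean non-carrier depth) is
bounded above by 0.75 for deletions; since the stated bound is physically
meaningful only for losses, duplications and CNVs use the mirrored bound
(> 1/0.75) and balanced or point events (INS/INV/TRA) are exempt.
Inversions additionally require a genotyped/ungenotyped sample ratio
> 0.4 (the alternative genotyped/total reading is behind
`inv_ratio_mode = "total"`) and a carrier supporting-pair fraction > 0.3.
Translocations inside user-supplied syntenic blocks are removed; synteny
computation itself is out of scope.

Clustering joins two calls of the same type and chromosome (chromosome
pair for interchromosomal translocations) when, for intervallic types,
reciprocal overlap >= 0.80 **and** both breakpoint offsets <= 250 bp
(conjunctive, in the style of standard SV site-list construction), or for
insertions/translocations when both breakpoint offsets are within 250 bp.
Connected components (single linkage — deterministic and standard for
site lists, rather than strict cliques) become consensus sites; the
representative interval is the per-coordinate lower median of members and
breakpoint precision is the maximum member offset from it. Tandem (CNV)
and dispersed (DUP) duplications are distinct types and never cross-merge.
Internal coordinates are 0-based half-open with conversion only at I/O
boundaries (VCF POS/END are 1-based with END inclusive).

Concordance is reported twice: the site-level fraction of consensus sites
supported by >= 2 tools (the natural reading of published per-type
agreement percentages) and the call-level fraction of calls in >= 2-tool
components; for sites seen by one or two tools these are related by
2r/(1+r). The weighted mean is over DEL/INS/INV/DUP, weighted by per-type
call counts.

# SV gene impact

The four scenarios (in gene, upstream-and-gene, downstream-and-gene,
whole gene) are positional — left/right on the reference, not strand-aware
— because they describe SV geometry rather than regulation. Spanned types
(DEL/DUP/CNV) use interval logic over the SV span; inversions and
translocations test each breakpoint for falling inside a gene (a gene
wholly inside an inversion without breakpoint contact is not counted).
Point insertions can only realize the in-gene scenario; interval-form
insertions (inserted length projected on the reference) are available
behind `ins_as_interval = TRUE`. A site hitting several genes contributes
to each (SV, gene) scenario count but only once to the percentage of
sites affecting genes, keeping percentages <= 100.

# Heterozygosity and duplications

`hetProfile()` computes per-sample het rates in 100-kb windows with 50-kb
steps by default (window sizes for this kind of profile are rarely
published; both are exposed). Windows with fewer than `min_sites` called
variants are flagged uninformative. Clusters are runs of qualifying
windows (het rate >= 10x the background rate, with an absolute floor of
0.05) merged across gaps up to one step, requiring >= 3 windows. The
duplication-concordance statistic counts a DUP/CNV call as concordant
when **the same accession** that carries the call shows an overlapping het
cluster — the sample-matching is the point of the diagnostic. The
denominator is per call by default; a region-level mode (calls merged
across samples) is available, as the published statistic's denominator
could be read either way.

# The synthetic cohort generator

`generateCohort()` emits a complete toy study — reference FASTA, GFF3 gene
models with codon-aware CDS (ATG, sense codons, stop), a multi-sample VCF,
per-caller SV call sets, an array-genotype subset and per-sample BED-graph
depth tracks — deterministically from a seed.

Genotypes follow a block-founder-haplotype model. Each chromosome is cut
into blocks (default 100 kb); within a block every inbred sample carries
one founder haplotype, and a site's minor-allele carriers are a union of
founder groups. The default "binary" scheme sizes the founder groups
1, 2, 4, ... plus a remainder so that **any** minor-allele sample count is
an exact subset sum: the realized MAF spectrum matches the requested bin
weights exactly, up to multinomial bin sampling and the rounding of
maf x n to whole samples. The "balanced" scheme (near-equal founder
groups) is the right choice when every haplotype must be shared by
several samples, e.g. imputation experiments. Founder membership is
correlated with subpopulation labels through a noise parameter, giving
mild population structure by default (which, realistically, also creates
long-range LD; cohorts for LD-decay experiments should use weak structure
or directly planted blocks).

Heterozygosity is planted at the genotype level: a background rate
(default 0.5%, matching the sub-1% residual level expected outside
duplicated regions) plus per-segment artefact rates (default 40%) inside
planted duplications for carrier samples, which also scale the depth
track by the segment's multiplier. Reads are never simulated — the
downstream analyses consume genotypes and depth, not alignments. Mock
callers drop truth calls at a false-negative rate, jitter breakpoints
with Gaussian noise, add false positives, and can be forbidden types
(the paired-end profile cannot emit tandem duplications; the read-depth
profile only sees copy-number-changing events), mirroring the
complementary blind spots of real tools.

Default cohort dimensions mirror the study design this toolkit targets:
102 accessions in 5 subpopulations, a MAF spectrum with 35% of sites
below 0.1 and 14% in [0.4, 0.5] (interior bins interpolated, as only the
end bins are typically printed), ~11x depth. Test and acceptance cohorts
scale the genome down (hundreds of kb to a few Mb, hundreds to thousands
of sites) so the whole suite runs in minutes; the statistics of interest
are planted rates and recovery properties, which do not require full-size
genomes.

What passing tests on this generator do **not** show: robustness to
alignment artefacts, indel left-normalization issues, caller-specific
genotype-likelihood behaviour, or LD patterns beyond block-haplotype
structure. The generator validates the pipeline's logic and arithmetic,
not the upstream callers.

# Numerical conventions and degenerate inputs

* Lower medians (the smaller central value at even counts) for consensus
  representatives — deterministic and insensitive to member order.
* MAF bins are left-closed/right-open with a closed final bin, assigned
  via `findInterval` to avoid floating-point edge surprises at 0.1/0.2/...
* Perfect LD is r² >= 1 − 1e-9; monomorphic pairs are undefined and
  excluded rather than zero.
* Empty inputs return empty tables (annotation summaries, cluster lists);
  undefined ratios (no duplication calls, no comparable genotypes) are
  flagged explicitly instead of returning 0/0.
* All site keys are (chrom, pos, ref, alt); duplicate keys are rejected by
  the `GenotypeMatrix` validity method.

# Interfaces

The package is a library: the exported functions plus `runPipeline()` /
`makeReport()` (a declarative config with schema validation, stage
toggles, a global seed, and a manifest with file checksums sufficient to
reproduce a run byte-identically) are the entry points, and
`scripts/acceptance.R` shows a complete scripted analysis. Problem sizes
used there — e.g. 50 replicates of the SV concordance experiment at
871 sites each, a 30-sample/10-Mb duplication cohort, 1000-site
imputation cohorts — were chosen as the smallest designs whose planted
effects are resolvable well above sampling noise.
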