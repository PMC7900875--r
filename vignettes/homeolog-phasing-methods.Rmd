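---
title: "Methods: subgenome phasing, homeolog expression and divergence dating in allopolyploids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subgenome phasing, homeolog expression and divergence dating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homeologr)
```

# The problem

Allotetraploids carry two parental chromosome complements (subgenomes M and
P, for the maternal and paternal diploid progenitors). When no reference
genome exists — the situation in *Ephedra*, the gymnosperm genus this
package was built around — subgenome evolution must be read from
transcriptomes alone: long-read isoforms phased against the diploid
progenitors' orthologous transcripts, short-read variant calls against a
single progenitor reference, and flow-cytometry genome sizes. `homeologr`
implements that analysis chain end to end, together with a synthetic data
generator that reproduces the statistical structure every stage assumes, so
the whole pipeline is testable without any external download.

# Diagnostic-SNP phasing

For each one-to-one orthogroup (OG) across five diploid progenitors
(maternal group `pr`, `re`; paternal group `eq`, `mi`, `mo`), a column of
the OG alignment is *diagnostic* when each group is fixed for a different
unambiguous base. Any gap or IUPAC ambiguity in any diploid disqualifies
the column — a conservative rule: a column that is not cleanly fixed
between the groups cannot separate subgenomes. Polyploid isoforms are
matched to their OG (shared 12-mer prefilter, then semi-global alignment
with match 2 / mismatch −3 / gap open 5 / extend 2 against the OG majority
consensus, identity floor 70%, minimum isoform length 300 bp mirroring the
full-length-read definition) and the isoform base is read at every covered
diagnostic column, scoring M sites and P sites.

Classification uses two thresholds with strict inequalities:

* fewer than `min_sites = 4` scored sites → **unassigned** (coding
  sequences carry little variation; four sites is the floor at which a
  call is considered safe);
* M-site proportion > 0.8 with ≥ 4 M sites → **M**; proportion < 0.2 with
  ≥ 4 P sites → **P**;
* anything else — boundary proportions of exactly 0.8/0.2 included — is a
  **recombinant** (chimeric molecule) and is removed from tabulation.

The min-site rule binds the *called* parent only: 3 M vs 20 P sites is a
valid P call. Per sample, an OG with both M- and P-called isoforms is
H~MP~, with only one side H~M~ or H~P~; percentages are of the sample's
expressed OGs, rounded half-up to integer percent (`round_half_up()`,
because printed tables conventionally round 0.5 up, unlike R's
round-half-even). Expression-pattern similarity between samples is the
Pearson correlation of the concatenated per-OG binary indicators (M
expressed, P expressed) over OGs expressed in at least one sample of the
pair; a zero-variance vector yields `NA`, never 0.

All coordinates in this package are 1-based, both internally and in
reports — the natural R convention, chosen to avoid a permanent
off-by-one hazard between code and output.

# Saturation (rarefaction) modelling

Uniform without-replacement subsamples of the isoform pool (default sizes
30,000–150,000 by 30,000, 3 replicates — the deep-pool design; synthetic
runs scale the sizes to the pool) are counted for expressed OGs (y₁) and
H~MP~ OGs (y₂), and a degree-2 polynomial is fitted by ordinary least
squares in log–log space over all replicate points jointly (replicates
carry real information; fitting on means would discard it):

$$\log y = a(\log x)^2 + b\log x + c.$$

With negative curvature, the vertex $-b/(2a)$ locates the saturating
depth and the fitted value there is the saturation value. The log base
defaults to natural log and is switchable to base 10; the vertex in raw
$x$ and all fitted counts are invariant to the choice, so nothing
scientific depends on it. Non-positive counts are dropped with a warning;
at least three distinct sizes must survive.

# Ks estimation and divergence dating

Homeolog pairs are codon-aligned through their proteins (global
Needleman–Wunsch under BLOSUM62, gap open 10 / extend 0.5, codons threaded
back through the protein alignment); codon columns containing a gap, a
stop or an ambiguous base are dropped. Synonymous distance follows
Nei–Gojobori (1986): per-codon synonymous site fractions from the
universal code (at each position, the fraction of the 3 possible changes
that preserve the amino acid; changes to stops count as nonsynonymous),
averaged over the two sequences; multi-hit codons contribute
pathway-averaged counts with every minimal mutational pathway weighted
equally, steps scored synonymous iff they preserve the amino acid; and a
Jukes–Cantor correction $K_s = -\tfrac{3}{4}\ln(1-\tfrac{4}{3}p_s)$,
undefined (saturated) at $p_s \ge 0.75$. The exhaustive
pathway-enumeration oracle in the test suite checks the implementation on
all 61 × 61 sense-codon pairs.

Ks values below 0.001 are excluded before peak detection (they reflect
allelic or assembly redundancy and create a spurious peak at zero; the
boundary value is kept — the exclusion is strict). Peaks are found with
univariate Gaussian mixtures fitted by EM (tolerance 1e-6 on the
log-likelihood, 10 random restarts per component count, degenerate runs
discarded) for k = 1…5, selected by
$\mathrm{BIC} = -2\log L + (3k-1)\ln n$. These EM settings are the
package's own choices; they are fixed, logged in every fit object, and
cross-checked against an independent mixture implementation (`mclust`) in
the tests.

A Ks peak converts to time as $t = K_s / r$ with
$r = 4.8\times10^{-9}$ synonymous substitutions per site per year (the
gymnosperm synonymous clock): a peak of 0.04 dates to ≈ 8.3 Ma. Dividing
by $r$ rather than $2r$ treats the peak as a per-lineage distance; the
two-lineage convention $K_s/2r$ is available via the `convention`
argument for users who prefer it.

# Alternative splicing without a genome

Each OG's isoform CDSs are merged progressively (longest first) by global
alignment; reference-gap columns contribute the incoming segment, so the
merged reference carries every segment present in any CDS exactly once
and is at least as long as the longest contributor. A CDS whose matched
columns fall below 90% identity against the growing reference conflicts
with it and is skipped with a warning (falling back, in the degenerate
case, to the longest CDS alone).

Isoforms are then aligned semi-globally to the merged reference —
terminal gaps are free, so partial coverage never fakes an event — and
each internal gap run **strictly longer than 51 bp** becomes one event:
isoform-side gaps are deletions, reference-side gaps insertions. Gap runs
separated by at most 2 aligned bases are fused before thresholding; the
fusion guards against alignment jitter splitting one biological event and
is exposed as `fuse_within` (0 disables it). Whether raw or fused runs
better match manual curation is genuinely open; fusion-on is the default
and documented. Events on recombinant or unassigned isoforms are excluded
from the per-subgenome tables (their subgenome is unknowable); OG shares
are reported to 2 decimals.

# SNP-based homeolog expression

Variant sites called against the maternal progenitor's transcripts pass
hard filters QD ≥ 2.0, FS ≤ 10.0, MQ ≥ 40.0, DP ≥ 30,
ReadPosRankSum ≥ −8.0, GQ ≥ 20 — the complements of the usual GATK
removal criteria, with boundary values passing (GATK filter-expression
semantics) and missing annotations passing their criterion (logged). At
sites where the parents are homozygous for different alleles, the
polyploid genotype is S~PM~ (heterozygous with both parental alleles),
S~PP~ / S~MM~ (homozygous like one parent), or autapomorphic (an allele
absent from both parents; excluded — such sites cannot be assigned to a
subgenome). Genes need ≥ 4 sites of the defining kind; when several
thresholds are met the precedence S~PM~ > S~PP~ > S~MM~ keeps classes
exclusive — heterozygous evidence is the direct signature of both
homeologs being present, so it outranks the homozygous classes.

For G~PM~ genes, the paternal expression fraction sums allele depths over
the gene's S~PM~ sites. Dominance uses the 0.6 rule with strict
inequalities: fraction > 0.6 → P-dominant, < 0.4 → M-dominant, the closed
band [0.4, 0.6] → conserved. The band is the mirror image of the 0.6
cutoff; no separate "conserved" threshold exists.

# Gene-tree screening

Gene trees (newick with bootstrap values as internal-node labels, the
RAxML convention) are treated as unrooted: a taxon set is a clade when
some edge bipartitions the leaves into the set and its complement. A
transcript is assigned M when the maternal taxa plus the transcript form
a clade and the paternal analogue does not (symmetrically for P); a clade
with bootstrap strictly below 60 excludes the tree (support of exactly 60
passes). When *both* augmented sets are clades the transcript attaches to
the backbone between the two groups — on an unrooted tree without an
outgroup, "sister to the maternal pair" and "sister to the paternal
triple" are then the same topology, so the transcript is reported
unresolved rather than erroring: the data genuinely cannot side it.

# Genome-size arithmetic

Ploidy is inferred as $2\times\mathrm{round}(1C/1C_{\mathrm{ref}})$
against a diploid calibrator, rejecting ratios farther than 0.25 from an
integer multiple; the monoploid size is $1Cx = 1C/(\text{ploidy}/2)$
rounded half-up to 2 decimals. A tetraploid is flagged *additive* when
its 1C value is within 5% (relative) of its parents' sum — the signature
of limited post-polyploidisation genome restructuring.

# The synthetic generator: what it emulates and what it does not

`simulate_progenitor_ogs()` draws each OG root as random sense codons and
places fixed inter-group differences on the stem separating the parental
groups (each site independently, probability `intergroup_divergence`,
default 0.02 — giving the ~13–17 diagnostic SNPs per isoform scale seen
in real data at the default 200-codon length); tips then accumulate
private Jukes–Cantor substitutions (`branch_sub_prob`, default 0.003).
Jukes–Cantor is the simplest exchange model consistent with the NG86
assumptions downstream; the fixed five-taxon topology
`((eq,(mi,mo)),(pr,re))` matters only through its two-group structure.
Polyploid isoforms copy the retained ancestral M or P haplotype per an
expression profile (by default 70% of OGs express both subgenomes, 15%
each one-sided — the H~MP~-dominated regime of real allotetraploid
samples), with i.i.d. base-exchange errors (default 0.002) and a
configurable fraction of single-breakpoint chimeras (default 0.02,
uniform breakpoint — the simplest mechanism that produces intermediate
M-proportions). Per-OG isoform counts are `1 + Poisson(mean − 1)`; real
per-OG distributions are unknown beyond their means, so the mean is a
parameter, not a law. Truth labels travel in a sidecar table, never in
the sequence ids the analysis consumes.

The allele-depth generator constructs S~PM~/S~PP~/S~MM~ sites in
proportions 0.77/0.12/0.11 (the observed site-class regime), draws S~PM~
allele depths binomially around each gene's true paternal fraction, and
populates the INFO/FORMAT annotations with a configurable fraction
failing exactly one hard filter. The true paternal fraction follows a
symmetric law — 80% uniform on [0.4, 0.6], 20% split evenly between
mirrored dominant tails — so dominance symmetry is a property of the
input, testable with binomial bounds.

Deliberately **not** emulated: PacBio homopolymer indel profiles,
read-level coverage structure, expression-level realism beyond the stated
laws, alternative-splicing truth (AS events are injected explicitly where
needed), and real phylogenetic branch-length heterogeneity. Passing tests
therefore demonstrate the *computational* correctness of every rule on
data with the assumed structure, not robustness to error modes the
generator does not contain.

# Numerical choices and degenerate inputs

* Alignment scores (2/−3/−5/−2 nucleotide; BLOSUM62 10/0.5 protein) are
  fixed package-wide; the identity floor (70%) decides "unmatched".
* EM restarts with vanishing standard deviation or weight are discarded;
  constant-valued input makes every restart degenerate and the fit
  errors out rather than returning a sham model.
* Mixture fits need ≥ 10 values; saturation fits ≥ 3 distinct positive
  sizes; empty diagnostic-site sets leave isoforms unassigned.
* `round_half_up()` is used wherever a printed percentage or pg value is
  produced; published tables are not uniformly rounded, so single
  percentage points may differ from any one printed table.
* All generators take explicit integer seeds; identical seeds give
  byte-identical outputs.

# Problem sizes

The bundled analysis scripts and the test suite run the full chain on 60
orthogroups × 200 codons with ~680 isoforms, two samples, and VCFs of a
few hundred sites; property tests use 12–20 OGs. These sizes keep every
stage's statistical checks (binomial bounds at α = 0.001, mixture
recovery over 100 replicates) well-powered while the whole suite stays
fast; nothing in the methods depends on scale beyond sampling noise.

# Known limitations

* NG86 with equal pathway weighting is one defensible Ks engine among
  several; ML codon models (GY94) would differ slightly at high
  divergence and are out of scope.
* The merged-CDS union is heuristic: mutually inconsistent segment orders
  fall back to the longest CDS with a warning rather than attempting a
  full multiple alignment.
* AS events cannot be subtyped (exon skip vs intron retention) without
  genomic introns.
* Saturation forecasts extrapolate a quadratic; beyond the fitted range
  they are summaries of the fit, not biology.
* Tree screening requires the transcript to be strictly nested inside a
  parental group; backbone attachments are honestly unresolved.
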