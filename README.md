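# homeologr

Subgenome phasing and homeolog-expression analysis for allopolyploid
transcriptomes without a reference genome.

Allotetraploids carry two parental subgenomes (maternal **M**, paternal
**P**). In groups with enormous, unsequenced genomes — *Ephedra* and other
gymnosperms are the motivating case — the only tractable windows onto
subgenome evolution are transcriptomes: long-read isoforms, orthologous
transcripts of the diploid progenitors, short-read variant calls against a
single progenitor reference, and flow-cytometry genome sizes. `homeologr`
implements that analysis chain as a tested R package:

* **Diagnostic-SNP phasing** — alignment columns fixed for different bases
  between the maternal and paternal diploid groups score each polyploid
  isoform's M and P sites; an isoform is called M when its M-site
  proportion exceeds 0.8 with ≥ 4 M sites, P below 0.2 with ≥ 4 P sites,
  and is otherwise a recombinant (removed) or unassigned. Orthogroups are
  tabulated as H<sub>MP</sub> / H<sub>M</sub> / H<sub>P</sub> per sample.
* **Saturation modelling** — subsampled discovery counts fitted with
  log y = a (log x)² + b log x + c; the vertex −b/(2a) gives the
  saturating depth and the fitted maximum.
* **Ks divergence dating** — Nei–Gojobori (1986) synonymous distances
  (pathway-averaged counts, Jukes–Cantor correction) between phased
  homeolog pairs; Gaussian-mixture peak detection with BIC selection
  (BIC = −2 log L + (3k−1) ln n); time t = Ks/r at r = 4.8×10⁻⁹
  synonymous substitutions/site/year.
* **Reference-free alternative splicing** — per-orthogroup merged-CDS
  union reference; indels strictly longer than 51 bp between isoform and
  reference are AS events, tabulated per subgenome.
* **SNP-based homeolog expression** — GATK-style hard filters
  (QD ≥ 2, FS ≤ 10, MQ ≥ 40, DP ≥ 30, ReadPosRankSum ≥ −8, GQ ≥ 20),
  S_PM/S_PP/S_MM site classes, G_PM/G_PP/G_MM gene classes (≥ 4 sites),
  paternal expression fraction from allele depths, dominance at the 0.6
  rule.
* **Gene-tree screening** — unrooted monophyly of {parental group +
  transcript} with bootstrap ≥ 60, cross-validating the SNP-based calls.
* **Genome-size arithmetic** — ploidy from 1C ratios, monoploid 1Cx
  values, parental additivity.
* **Synthetic data generator** — progenitor orthogroups, polyploid
  isoforms (errors, chimeras), allele-depth VCFs and gene trees with full
  truth tables, so every stage is testable offline.

## Worked example

```r
library(homeologr)

cfg <- sim_config(seed = 42, n_ogs = 60, samples = c("S1", "S2"))
ogs <- simulate_progenitor_ogs(cfg)
iso <- simulate_polyploid_isoforms(ogs, cfg)
asg <- phase_isoforms(iso$isoforms, ogs,
                      samples = setNames(iso$truth$sample, iso$truth$isoform_id))
tabulate_homeologs(asg)
#>   sample total H_MP H_M H_P H_MP_pct H_M_pct H_P_pct
#> 1     S1    60   43   6  11       72      10      18
#> 2     S2    60   43   7  10       72      12      17
```

72% of expressed orthogroups show homeolog pairs from both subgenomes
(H_MP) in each sample, with the one-sided classes roughly balanced —
the unbiased-expression regime the generator encodes. Phasing recovers
99.3% of the 680 simulated truth labels at the default 0.2% error rate.
Dating a subgenome-divergence Ks peak:

```r
divergence_time(0.04, rate = 4.8e-9)$time_ma
#> [1] 8.333333
```

The numbered scripts under `analysis/` run the complete study on the
synthetic dataset — simulation, phasing, saturation, Ks dating, splicing,
SNP expression, tree screening, genome-size arithmetic — each writing its
tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_phase_homeologs.R   # ... through 08_genome_size.R
```

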