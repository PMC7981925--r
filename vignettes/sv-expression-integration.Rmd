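---
title: "Integrating somatic SV breakpoints with gene expression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating somatic SV breakpoints with gene expression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svexpr)
```

## The problem

Somatic structural variants (SVs) in cancer genomes can deregulate genes
without touching their coding sequence: a rearrangement can reposition an
enhancer next to a gene (enhancer hijacking), break up a topologically
associated domain (TAD) and rewire cis-regulation, amplify or delete the
locus, or fuse two genes. Given a cohort profiled for both whole-genome SVs
and RNA-seq expression, `svexpr` catalogs genes whose expression is
recurrently shifted when an SV breakpoint lies nearby, separates that
signal from copy-number dosage, and annotates candidate mechanisms.

Each SV contributes two breakpoints (the fused coordinates, called mates).
The unit of evidence is a breakpoint falling in a *region window* relative
to a gene.

## The model

For each gene $g$ and region window, a gene-by-sample breakpoint matrix
$B_{gs}$ is built: $B_{gs} = 1$ if any breakpoint of sample $s$ falls in
the window of $g$, else 0. The four windows are 100 kb upstream, 100 kb
downstream, the gene body, and the gene body plus 1 Mb flank on each side.
Upstream and downstream are strand-aware: "upstream" is measured from the
transcription start site (TSS), which is the `start` coordinate on the $+$
strand and the `end` coordinate on the $-$ strand. All internal
coordinates are 0-based half-open (BED convention); SV caller positions
are assumed 1-based and converted once on read.

For the 1 Mb flank window a *relative distance metric* can replace the
binary entry:

$$ w = 1 - d / 10^6, \qquad
   d = \begin{cases} 0 & \text{breakpoint inside the gene body} \\
       \min(|pos - start|, |pos - end|) & \text{otherwise,} \end{cases} $$

taking the per-sample maximum over breakpoints. Nearby breakpoints thus
carry full weight while breakpoints up to 1 Mb away retain some influence.
The linear form is the simplest function with those two properties; a
breakpoint exactly at the window edge is in-window with weight 0, so the
half-open window convention and the weight formula agree at the boundary.

Expression is then modeled per gene by ordinary least squares:

$$ y_s = \beta_0 + \beta_{sv} B_{gs} + \sum_k \gamma_k \,
   \mathbb{1}[\text{type}(s) = k] \; (+\; \delta \, \mathrm{CNA}_{gs}) +
   \varepsilon_s $$

with a two-sided $t$-test on $\beta_{sv}$. Two model families are fit —
with and without the gene-level CNA covariate — because rearrangements
travel with copy-number changes, and associations that survive CNA
correction are the ones most plausibly cis-regulatory. Multiple testing is
controlled per (window, model) family with Storey–Tibshirani q-values:
$\hat\pi_0$ is estimated on the $\lambda$ grid $0.05, 0.10, \dots, 0.95$
with a cubic smoothing spline (3 df) evaluated at $\lambda = 0.95$ and
clamped to $(0, 1]$, falling back to $\pi_0 = 1$ (exactly
Benjamini–Hochberg) when fewer than 4 grid points are usable. Genes whose
breakpoint column is constant, or altered in fewer than
`min_altered_samples` samples (default 1), are skipped and excluded from
the FDR family. Samples with missing expression or CNA are dropped per
gene; batch correction, if needed, is the user's responsibility upstream
of the screen.

## Mechanism annotation

**Associations.** For each (gene, sample) with an in-window breakpoint,
one association is kept, using the breakpoint closest to the TSS (ties:
lower coordinate, then sv_id — determinism matters for reproducible
output). The mate breakpoint is *distal* if it is on another chromosome or
outside the gene's 1 Mb flank.

**Enhancer hijacking.** For distal associations the region within 1 Mb of
the mate breakpoint is scanned for enhancers. The rearrangement is modeled
as placing the nearest such enhancer at

$$ d_{new} = d(\mathrm{bp}_1, \mathrm{TSS}) + d(\mathrm{bp}_2,
   \mathrm{enhancer}) $$

from the gene — the only geometry consistent with the two breakpoints
being fused. An event is called when $d_{new} \le 500$ kb and $d_{new}$ is
smaller than the distance to any native enhancer within the 1 Mb
*upstream* window of the unaltered gene (nearest-edge distance; an
enhancer overlapping the TSS counts as distance 0; no native enhancer
means $+\infty$). The upstream restriction applies to the native scan
only; enhancer orientation is ignored, as enhancers act
orientation-independently. Enrichment of events among associations whose
sample over-expresses a significant gene is tested with a Pearson
chi-squared test (1 df, no continuity correction).

Over-expression throughout uses one rule: the sample's expression exceeds
the gene's cross-sample median by more than 0.4 cross-sample standard
deviations, and the gene is significant in the screen (q < 0.10 by
default).

**TAD disruption.** Each breakpoint is assigned to the TAD containing it;
with nested annotations the smallest containing TAD wins (most specific).
Both breakpoints in one TAD is *preserving*; different TADs (or
chromosomes) is *disrupting*; a breakpoint in a TAD gap leaves the SV
*unassigned* — a third class rather than a forced binary, because real TAD
BEDs have gaps. Enrichment of disruption among SVs linked to
over-expressed significant genes is again chi-squared, with unassigned SVs
excluded from both groups.

**Fusion corroboration.** RNA-seq fusion candidates (gene5, gene3, sample)
gain `support` when any of the sample's breakpoints lies inside either
partner's gene body, and a `high_expression` flag when either (1) the
fusion occurs in at most two samples and every harboring sample
over-expresses at least one partner (> 0.4 SD rule), or (2) either partner
has a positive association at p < 0.01 in the CNA-corrected model in the
distance-weighted flank window or the gene-body window. Recurrence is
counted on the unordered pair; the 5'/3' order is kept for reporting.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the screen assumes,
so every stage is testable without external data. Genes (20 kb bodies) are
placed every 250 kb on 2–8 synthetic chromosomes with 2 Mb margins; TADs
tile each chromosome (750 kb domains, 50 kb boundary gaps — the scale of
mammalian Hi-C maps); enhancers are scattered at 2 per Mb. Samples carry a
background SV process (2.5 SVs per sample by default) in which the second
breakpoint falls in the first breakpoint's TAD with probability 0.7 and is
uniform otherwise, mimicking the preponderance of short-range
rearrangements. Expression is

$$ y_{gs} = \mu_{g,\mathrm{type}(s)} + 0.5\,\mathrm{CNA}_{gs} +
   \beta\,\mathbb{1}[B_{gs} > 0] + \varepsilon_{gs}, \qquad
   \varepsilon \sim N(0, 1), $$

Gaussian on the log scale to match the OLS model used for calibration.
Effect genes (5% by default, $\beta = 2$ SD) receive 8 planted SVs whose
near-breakpoint is uniform in the flank window and whose mate follows the
*same law as the background process* — so in mechanism-free scenarios the
SV geometry of effect and non-effect genes is exchangeable, which is what
makes the enrichment null tests meaningful. Setting
`cna_confounding_strength` adds CNA dosage in breakpoint-carrying samples,
coupling SV presence to expression through the CNA slope: the uncorrected
model then flags large numbers of genes that the CNA-corrected model
correctly discards. The `hijack` and `tad` presets replace the planted
SVs' geometry with engineered ones (mate 50 kb from a donor enhancer on
another chromosome with natives cleared, or mate four TADs away,
respectively). The truth table records every planted effect and mechanism;
runs are byte-identical per seed.

What the generator does *not* emulate: realistic SV length/type spectra,
karyotype-scale events, clustered breakpoints (chromothripsis),
tissue-specific enhancer activity, and expression heteroscedasticity.
Passing tests therefore certify the statistical machinery under the
model's own assumptions, not performance on any particular real cohort.

## Numerical and design choices

- Chromosome names are normalized to the `chr`-prefixed dialect and
  mitochondrial aliases unified, since SV tables and BEDs commonly
  disagree; SVs with both breakpoints at identical coordinates carry no
  information and are dropped with a warning.
- Collinear cancer-type indicators (e.g. a type emptied by per-gene
  missing-value filtering) are dropped deterministically by the QR pivot in
  level order; if the breakpoint term itself is aliased the gene is
  skipped, never silently refit.
- The hypergeometric upper tail is used directly for one-sided gene-set
  overlap tests; the 2x2 chi-squared statistic is the closed-form Pearson
  formula, so degenerate margins return NA rather than an error.
- Cancer types with a single sample are retained; their indicator absorbs
  one observation.
- Test-suite and calibration problem sizes: unit oracles run on
  10–20-gene instances; calibration and recovery use the full reference
  conditions (1000 genes, 200 samples); the 50-seed enrichment null uses
  240-gene, 120-sample cohorts, which give several hundred linked
  associations per seed — enough for the chi-squared null to be smooth.

## Known limitations

- **Per-SV TAD enrichment carries a dispersion confound.** A
  TAD-disrupting SV has two breakpoints in distant neighborhoods and so
  covers roughly twice as much genomic territory as a preserving SV, whose
  breakpoints sit within one TAD. It is therefore about twice as likely to
  have *some* breakpoint within 1 Mb of an over-expressed significant
  gene, even when disruption has no regulatory effect at all. In
  mechanism-free simulations the disrupting fraction among linked SVs runs
  ~0.35 versus ~0.24 in the background, and the enrichment p-values are
  left-skewed rather than uniform. The per-association hijack enrichment
  has no such confound (each association is a single breakpoint-gene
  pairing) and its null is uniform. TAD enrichment p-values should be read
  with this in mind — a conclusion that applies to this enrichment design
  generally, not just to this implementation.
- The distance-weight form is a modeling choice; any monotone decay with
  $w(0) = 1$, $w(1\,\mathrm{Mb}) = 0$ would satisfy the same qualitative
  contract.
- The enhancer step treats all enhancers as active in every sample;
  tissue-matched enhancer catalogs would sharpen the calls.
- VCF BND records are not parsed directly; convert to the five-column
  breakpoint table first.

## A worked run

```{r example, eval = FALSE}
co <- simulate_cohort(preset_sim_config("hijack", seed = 1))
screen <- run_association_screen(co$expr, co$bp_matrix, co$sample_annot,
                                 co$cna, models = "type_plus_cna")
sig <- screen$gene_id[screen$significant & screen$t_stat > 0]
assocs <- gene_sv_associations(co$genes, co$svs, "flank1mb",
                               samples = co$sample_annot$sample_id)
calls <- call_hijacks(assocs, co$genes, co$enhancers)
hijack_enrichment(calls, overexpressed_flags(calls, co$expr, sig))
```

The same stages run from the shell through the bundled CLI
(`inst/cli/svexpr.R`) or in one step from a YAML config via
`run_pipeline()`, which writes every stage output plus a manifest with
input digests for provenance.
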