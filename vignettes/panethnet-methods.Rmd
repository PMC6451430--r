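---
title: "panethnet: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{panethnet: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panethnet)
```

# The analysis

Autophagy recycles cellular components; its selective arm uses receptor and
adaptor proteins — p62/SQSTM1, the LC3 family, and ATG16L1 — to deliver
specific cargo to the autophagosome. When autophagy is impaired in
intestinal epithelium (loss of *Atg16l1*), Paneth cells malfunction. If a
protein accumulates in the impaired background *and* is a plausible cargo of
the selective-autophagy machinery *and* its transcript did not change
correspondingly, the parsimonious explanation is failed autophagy-mediated
degradation. `panethnet` operationalizes that chain of reasoning as a
deterministic pipeline over eight input tables, with each inferential step a
separately exported and separately tested function.

# Stage models and their assumptions

## Differential abundance

Each protein carries per-replicate normalized label-free intensities for the
wild-type and knockout conditions (three biological replicates each by
default). The gate is the conjunction

* one-factor ANOVA `P < 0.05` (strict) — for two conditions this is the
  equal-variance two-sample t-test, `F = t^2`;
* absolute relative fold-change `>= 2` (inclusive);
* unique peptides `>= 2` (inclusive).

No multiple-testing correction is applied at this stage: the published
workflow gates on the raw P value here (FDR control belongs to the upstream
spectral identification, which this package consumes, not computes).
Assumptions worth knowing:

* **Scale of the ANOVA.** Whether the original pipeline tested raw or
  log-scale intensities is not stated. We default to log2, standard for
  label-free data where variance grows with intensity, with
  `anova_scale = "raw"` available. An intensity floor (default: half the
  smallest nonzero intensity in the table) guards zeros before the log.
* **Scale of the fold-change.** Computed on arithmetic means of the
  untransformed normalized intensities, matching the convention of
  Progenesis-style exports, and stored signed: `KO/WT` when the knockout
  mean is at least the wild-type mean, `-(WT/KO)` otherwise, so the
  magnitude is always `>= 1` and `log2fc = sign * log2(|FC|)` is
  unambiguous.
* **Degenerate variance.** Zero within-group variance with equal means gives
  `p = 1` by convention; with unequal means, `p = 0` (perfect separation
  passes any alpha). This makes the zero-noise synthetic limit exact.

## Orthology

Mouse accessions are mapped to human through an InParanoid-style pair table.
One-to-many mappings expand rows — the motivating dataset's 283 mouse
proteins become 284 human orthologues — and the abundance direction and
log2FC are copied unchanged. Many-to-one collapses (several mouse proteins,
one human accession) have no published rule; we keep the representative with
the largest `|log2fc|`, because it preserves the "altered" call, and log
every collapse. Unmapped proteins are reported, never silently dropped. The
default confidence cutoff of 1.0 is the InParanoid seed-orthologue score;
lower it to admit co-orthologue expansions.

## Autophagy-target prediction

Four evidence channels feed one deduplicated evidence table:

* **experimental** — membership in per-receptor interactor lists (curated
  ARN-style exports);
* **database_list** — membership in an iLIR-style list of known
  LIR-containing proteins (LC3 channel);
* **motif scans** — the LC3 channel scans for a LIR motif; the default is
  the extended xLIR definition
  `[ADEFGLPRSK][DEGMSTV][WFY][DEILQTV][ADEFHIKLMPSTV][ILV]`, with the
  canonical core `[WFY]xx[LIV]` also provided. The p62 channel scans a
  user-supplied recognition motif: the published analysis cites but does not
  print its p62 motif, so the package deliberately ships **no authoritative
  default**; the synthetic generator uses the clearly labelled stand-in
  `[RK][RK]x[WFY][LIV]`.
* **ddi** — domain–domain interaction inference for ATG16L1: a candidate is
  predicted when it carries a domain forming a known interacting pair
  (DOMINE-style, stored unordered) with one of ATG16L1's own domains, which
  are read from the domain table under the configured accession rather than
  hard-coded.

The scanner treats a motif as positional alphabets over the 20 standard
residues; `X` in a sequence is legal but satisfies only unrestricted
positions. All overlapping hits are reported. PSSM scoring of LIR strength
is out of scope — membership is binary, as in the motivating analysis.

The 7-cell Venn partition over the three receptor target sets reports the
fraction of multi-targeted proteins. A hypergeometric enrichment of the
targeted set (`target_enrichment()`) is available but labelled exploratory:
the published `P = 0.049`/`P = 0.043` values have an unstated background
universe and are therefore not reproducible quantities.

## Process trends

A curated effect table links proteins to GO biological-process terms with an
activation/inhibition sign and an intestinal-context flag (out-of-context
terms are discarded before counting). The contribution of a (protein,
process) link is the product of abundance direction and effect sign:
more-abundant activators and less-abundant inhibitors push a process up;
the other two combinations push it down. A process is **upregulated** when
strictly more than 70% of its contributions are stimulatory,
**downregulated** when strictly more than 70% are inhibitory, and **dual**
otherwise. Two deliberate readings:

* **Exactly 70% is dual.** The published wording covers "more than 70%"
  (directional) and "less than 70%" (dual) but not equality; dual is the
  conservative completion, and the boundary is tested explicitly.
* **The contribution unit is the (protein, process) link**, not the
  receptor–protein edge: the published apoptosis arithmetic (19 of 25
  contributions inhibitory, 76%, downregulated) and DNA-repair arithmetic
  (5 of 7 stimulatory, upregulated) count each annotated protein once per
  process regardless of how many receptors target it. A protein annotated on
  several processes contributes independently to each.

The exported network is strictly tripartite — receptor→protein edges typed
`targets` (one per distinct pair), protein→process edges typed
`activates`/`inhibits` — as SIF, GraphML and a node-attribute TSV for
Cytoscape.

## Cross-omics concordance

For each targeted differential protein we pair the protein log2FC with the
transcript log2FC (through an optional identifier map). Transcripts are
differentially expressed when `|log2FC| >= 1` and `q <= 0.05` (inclusive,
as printed). The attribution rule: when the two log2FCs differ by strictly
more than 0.7 the protein change cannot be explained by transcription and is
attributed to impaired autophagy-mediated **turnover**; otherwise it is
**transcriptional**; missing transcripts give **no_transcript**. The
difference is taken on signed values (`|p − t|`), which is symmetric under
negating both sides; comparing absolute values instead would change calls
only when the two directions disagree, a case the strict rule already sends
to turnover under either reading for differences above 0.7. Transcripts
failing the DE gates still contribute to the difference — they are merely
flagged — because the published counting distinguishes "also differentially
transcribed" (44/66) from "difference above cutoff" (40/44).

## Marker enrichment

The probability of observing at least `k` markers in a DE list of `n` genes
drawn from a universe of `N` containing `K` markers is the exact upper-tail
hypergeometric sum, computed in log space (`lgamma`-based binomial
coefficients, log-sum-exp reduction) so values at the published magnitudes
(`5.1e-57`) remain finite and positive; `k = 0` returns exactly 1. The
published universe sizes are unstated, so those exact p-values are treated
as non-reproducible; the package makes the universe an explicit argument and
defaults it, in the pipeline, to all genes detected in the transcript table.
Markers absent from the universe are excluded from `K` with a note. Gene
symbol normalization is the caller's responsibility (no remote lookups).

# The synthetic world

`scenario_spec()` states the world the generator emulates; its defaults are
the study's printed fractions used as generator parameters, not as claims
about new data: 283 differential proteins with 70% up, exactly one 1:2
orthologue expansion (283→284), 41% of the 284 targeted with 19%
multi-receptor, 16 processes with planted majorities, 66/116 targets
annotated with effects, a turnover subset at a planted log2FC difference of
1.5, and 83 markers of which 56 sit in the DE transcript list. Values the
study does not state were fixed once at realistic magnitudes:

* `n_proteins = 2000` — a typical organoid label-free depth for the quoted
  instrumentation era;
* `noise_sd = 0.25` (log2 replicate scatter, i.e. ~19% CV) — ordinary
  label-free reproducibility;
* planted `|log2FC|` uniform on [2.2, 4.2] — the generator's contract is
  that planted differential proteins pass the gates at the stated noise, so
  separations are drawn with margin above the FC threshold;
* base abundances uniform on log2 [18, 26], intensities log-normal around
  them.

Ground-truth bookkeeping records every planted fact. Two constructions make
downstream recovery exact rather than approximate: transcripts are planted
relative to the log2FC the pipeline will *observe* (ratio of arithmetic
replicate means), so turnover attribution is deterministic at any noise
level; and sequences are rejection-sampled so that non-target proteins
contain zero motif hits ("no accidental motifs"), with motif instances then
inserted only into designated targets. The LIR motif used for planting is
xLIR — the canonical core `[WFY]xx[LIV]` is too permissive to keep random
sequences clean, which is exactly why iLIR-style scans use the extended
definition.

What a green test does **not** establish: real label-free data have
missing-value structure, intensity-dependent variance and batch effects the
generator does not emulate; real orthology, interactor and curation tables
carry biases and gaps. The synthetic world validates the *logic* of every
stage against planted truth, not the biology of any particular dataset.

# Numerical and interface choices

* All writers emit doubles as `%.17g`, so every reader/writer pair
  round-trips bit-losslessly and repeated runs are byte-identical — at the
  cost of long decimal strings in the TSVs.
* Evidence tables are sorted on (protein, receptor, evidence type, detail)
  at write time; all other outputs have fixed column order and row sort, so
  outputs can be diffed across runs.
* Column dialects for abundance tables are explicit configuration
  (`abundance_dialect()`), never sniffed; the strict dialect rejects missing
  intensity cells with the offending row number, the impute dialect fills
  them with half the smallest nonzero intensity. How the original software
  handled missing values is unstated, hence the explicit switch.
* The seed governs fixture generation only; the pipeline itself is
  deterministic given its inputs.
* One-factor ANOVA is computed from group sums of squares with the p-value
  from the F distribution; the test suite cross-checks it against the
  independent t-test and `aov()` routes.
* The command-line wrapper (`inst/scripts/panethnet.R`) is a thin layer over
  the exported functions for shell use; the functions are the primary
  interface.

# Known limitations

* Target prediction is membership-based: no LIR position-specific scoring,
  no ubiquitination-site prediction, no structural docking.
* The per-protein contribution reading of the 70% rule is implemented
  because it reproduces the published arithmetic, but the alternative
  (counting receptor–protein edges) is a genuine ambiguity.
* The p62 motif must be supplied by the user; results for that channel are
  only as good as the supplied pattern.
* Published p-values that depend on unstated background universes (target
  enrichment, marker enrichment) are reported from explicit, configurable
  universes and will not numerically match the originals.

```{r example, eval = FALSE}
bundle <- generate_scenario(scenario_spec(seed = 7))
fx <- write_fixture_set(bundle, tempfile("fixtures"))
res <- run_pipeline(fx$config)
res
summary(res)
```
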