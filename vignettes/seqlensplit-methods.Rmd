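---
title: "Length-threshold splitting of FASTA datasets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Length-threshold splitting of FASTA datasets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqlensplit)
```

## The procedure

`seqlensplit` partitions a FASTA dataset at a length threshold and profiles
the resulting length distributions. The procedure is deterministic and has
no statistical model to fit; what it guarantees is a set of exact
conservation properties:

* **Completeness.** Every input record appears in exactly one of the two
  output files; concatenating them recovers the input record set, with
  relative order preserved within each side.
* **Boundary rule.** A record of length `c` (the cutoff) always goes to the
  above side; length `c - 1` always below. At the default `c = 200` the
  sides are the familiar "above 199 bp" / "below 200 bp" partition used when
  screening assembled transcripts against submission minima.
* **Length definition.** The length of a record is the character count of
  its residue string. Gap (`-`) and stop (`*`) symbols count: the tool
  partitions, it does not validate alphabets, and silently excluding symbols
  would change the split in ways a user cannot see. For the same reason
  zero-length records are legal; they always fall below any cutoff.
* **Count conservation in plots.** Each histogram's bin counts sum to the
  size of the partition side it depicts.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `cutoff` | 200 | length threshold, in residues; ≥ cutoff is "above". 200 is the conventional transcript minimum; 100 is typical for ORF/peptide work. |
| `seq_kind` | nucleotide | selects the unit label only: `bp` (nucleotide) or `aa` (protein). Parsing is identical for both. |
| `wrap_width` | 60 | residues per line in written FASTA; any positive value round-trips identically. |
| `show_plots` | FALSE | when TRUE, plots are additionally shown on an interactive device; files are always written off-screen first, so pipelines never need a display. |
| `plot_backend` | TkAgg | display-backend identifier (`TkAgg`, `MacOSX`, `Agg`); it affects interactive display only, never the saved PNGs. |

Output names are fixed conventions so downstream steps can rely on them:
`seq_above{c-1}{unit}.fasta`, `seqs_below{c}{unit}.fasta`,
`seq_length_stats_by_threshold_{c}.txt`, and four PNGs
(`seq_length_distribution_{side}{...}.png` with a `_log` suffix for the
log-scale pair, the below-log file carrying a `seqs_` prefix). The mixed
`seq_`/`seqs_` prefixes are kept deliberately for compatibility with the
established names, inconsistent as they are. With `--prot` the unit in all
names and labels becomes `aa` while the `.fasta` extension is kept — the
unit substitution reading of "protein output", chosen because changing the
extension would break downstream tools expecting `.fasta`. When no output
directory is given, one is derived as `{input-stem}_{nt|prot}_{cutoff}`
next to the input — underscore-joined in that order, so runs at different
cutoffs or sequence kinds never collide.

## Numerical and rendering choices

* **Binning.** The histogram uses width-1 bins centred on each integer
  length when the observed range spans ≤ 100 distinct values, and 50
  equal-width bins otherwise. The two regimes keep single-residue resolution
  at peptide scale (40–100 aa) while staying readable on heavy-tailed
  transcript distributions spanning thousands of bp. Bins are
  left-closed/right-open with the last bin closed, so integer lengths at
  internal equal-width edges are counted exactly once.
* **Log scale.** "Log" means a logarithmic (base 10) *count* axis over a
  linear length axis — the convention for heavy-tailed length
  distributions, where the linear view is dominated by the mode and the log
  view reveals the tail. Zero-count bins are kept in the spec; on the log
  axis they are simply drawn without a bar (bars rise from a floor of 0.8
  so single-count bins remain visible).
* **Degenerate inputs.** An empty FASTA is valid: both output FASTA files
  are written (empty), the stats file reports zero counts with `N/A`
  extremes (never 0, which is a legal length), and no plots are produced —
  each skipped plot emits one warning. A one-sided input produces the two
  plots of the populated side plus two warnings.
* **Error contracts.** A missing input path fails with a message containing
  `No such file or directory` (exit status 1 at the CLI); a missing `-i`
  flag is a usage error (`the following arguments are required: -i/--input`,
  exit status 2); `--nt --prot` together is a usage error. Outputs are
  overwritten without prompting — reruns are idempotent and byte-identical,
  which suits pipeline use.

## What the synthetic generator emulates

The package tests itself against `fixture_spec()`/`generate_fasta()`
fixtures rather than downloaded data. The default length model is a
log-normal (meanlog 6, sdlog 1, truncated to ≥ 1 and rounded), whose median
`exp(6) ≈ 403` and heavy right tail mimic the shape of de novo transcriptome
assembly length distributions and place substantial mass on both sides of
the 200 cutoff, so a default fixture exercises all four plots. Uniform and
exact-ladder models cover boundary and inventory checks; edge-case flags
inject zero-length records, duplicate identifiers and CRLF line endings.
Generation is fully seeded: one spec + seed is one byte-exact file, and the
caller's RNG stream is left untouched.

What the generator does *not* emulate: realistic base/amino-acid
composition (residues are i.i.d. uniform over a minimal alphabet), multiple
isoform length modes, N-content structure, or very large inputs. Passing
tests therefore demonstrate the splitting/stats/plotting contracts — which
depend only on lengths and headers — not performance or composition-aware
behaviour on real assemblies. Test problem sizes (up to 1000 records for
property suites, 5000 for distribution checks, 10 000 lengths for binning
oracles) were chosen as the smallest sizes at which the distributional
checks are stable.

## Known limitations

* FASTA only: no FASTQ, no gzip/bgzip transparent decompression.
* No N50/median/mean metrics — those are well served by existing stats
  tools; this package's summary is deliberately the count/min/max set tied
  to the split.
* Single cutoff per run; no simultaneous min-and-max range filtering.
* Interactive display (`show_plots = TRUE`) degrades to a warning on
  headless systems; the saved PNGs are unaffected.
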