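---
title: "Hairpin-based miRNA discovery from small RNA sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hairpin-based miRNA discovery from small RNA sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germmir)
```

## The problem

Plant microRNAs (miRNAs) are ~21-nt regulatory RNAs excised from
stem-loop precursors. Deep sequencing of a small RNA library yields
millions of short reads of which only a small fraction are genuine
miRNAs; the rest are degradation products of rRNA/tRNA/snRNA/snoRNA,
siRNAs, fragments of protein-coding transcripts, and noise. germmir
implements the classical discovery pipeline for this setting — the one
used for surveys of germinating seed and similar tissues:

1. **clean** raw reads (3' adapter location and trimming, 5'-adapter
   contaminant removal, mean-quality filter, polyA removal, 18–30 nt
   insert window),
2. **collapse** to unique tags with counts and drop tags seen once,
3. **map** tags to the genome by perfect full-length matching on both
   strands,
4. **annotate** mapped tags against ncRNA references and a gene model,
5. identify **conserved** miRNAs against a miRBase-style reference,
6. predict **novel** miRNAs by folding genomic windows around
   unannotated tags and applying hairpin criteria including the MFEI,
7. **confirm** candidates across two independently sequenced libraries,
8. predict **targets** with plant-style positional duplex rules.

## The hairpin model and its criteria

A candidate precursor is the genomic context of a mapped read, folded
into its minimum-free-energy (MFE) secondary structure. The miRNA*
span is derived from the pair table as the duplex partner of the mature
with two-nucleotide 3' overhangs on both strands — the signature left
by DCL1 processing. A candidate is accepted only when all of the
following hold:

* the window folds into a stem containing the read (`crit_hairpin`),
* the read lies entirely on one arm — a read across the terminal loop
  is rejected (`crit_one_arm`),
* at most **6 unpaired nucleotides** in the miRNA/miRNA* duplex,
  counting bulges and internal-loop residues on the mature strand
  (`crit_duplex`),
* no terminal-loop residue and no helix break inside the miRNA or
  miRNA* (`crit_clean`),
* mature length **20–22 nt**, miRNA-to-miRNA* separation **5–240 nt**,
  MFE **≤ −20 kcal/mol**, and **MFEI > 0.85** (`crit_mature_len`,
  `crit_loop_dist`, `crit_mfe`, `crit_mfei`).

The **minimal folding free energy index**

$$\mathrm{MFEI} = \frac{|\mathrm{MFE}|/L \times 100}{\mathrm{GC\%}}$$

normalises folding energy by length and base composition; genuine
plant pre-miRNAs typically exceed 0.85 while tRNA/rRNA/mRNA hairpins
stay below it.

```{r}
mfei(-42.5, 100, 50)
mfei(-46.56, 120, 40)
```

All statistics (MFE, MFEI, GC%, A+U%) refer to the *trimmed precursor*:
after the window fold, the enclosing stem-loop around the mature/star
duplex is excised (with a 2-nt margin for the star overhang) and
refolded. This removes the arbitrary influence of window flanks on
composition statistics. Because the genomic windows anchored at a read
are identical whichever library produced the read, the trimmed
precursor — and hence the MFEI — is reproducible across libraries,
which the cross-library identity confirmation relies on.

Two operational formalisations deserve note, since prose descriptions
of "an appropriate stem-loop" and "no loop or break" leave room:

* *one arm*: every paired mature position must have its partner outside
  the mature span, and all partners on the same side;
* *no loop or break*: the terminal loop (the region inside the
  innermost pair of the stem) must not intersect the mature or star
  cores (the 2-nt 3' overhangs are excluded — the star overhang
  legitimately abuts the loop on the 3' arm), and duplex partners must
  stay within the opposite span with a ±3-nt bulge allowance.

Two further pipeline-level rules follow common practice: the mature
read must carry at least 50% of all read counts mapped inside the
precursor (dominance), and overlapping accepted candidates are
collapsed to one per locus. The collapse deliberately ignores strand:
a planted stem-loop is near-palindromic, so the identical hairpin is
usually recovered from both genomic strands, and keeping both would
double every downstream count. Ties are broken by MFEI, then mature
count, then coordinate — all library-independent quantities.

## Folding engines

Folding is a pluggable contract: sequence in, dot-bracket plus MFE in
kcal/mol out. When the ViennaRNA `RNAfold` binary is on the PATH it is
used (batched, one process call per stage); otherwise the package falls
back to its built-in deterministic nearest-neighbour model (Rcpp): a
Zuker-style DP with a 6×6 helix stack table in integer
decikilocalories, logarithmic hairpin/bulge/interior penalties, a flat
multibranch penalty, no dangles, interior loops capped at 30 nt, and a
fixed tie-break order. The built-in engine's energies are rescored
exactly by an independent loop-decomposition oracle in the tests, and
RNAfold structures are rescored by `RNAeval`. No acceptance decision
depends on a specific engine's energies except through the user-visible
thresholds, and every planted construct in the synthetic data passes or
fails its designed criterion under either engine by construction.

## Target rules

Target sites are ungapped antiparallel duplexes, positions numbered
1..L from the miRNA 5' end; G:U wobbles count **0.5** mismatches in the
numeric rules but are pairings (not mismatches) in the positional
rules. A hit must satisfy: total score ≤ 4; no run of more than two
adjacent full mismatches; no adjacent full mismatches in positions
2–12; no full mismatch at positions 10–11; score over positions 1–12
≤ 2.5; and duplex energy ≥ 75% of the miRNA's perfect-complement
energy under the shared stack table. Strict mode (the default) further
requires total score ≤ 3 — including wobble halves, so two mismatches
plus three wobbles (3.5) fails strict. Scoring uses integer
half-mismatch units and integer decikilocalories, so the compiled
scanner and the per-pair reference functions agree bit-for-bit; the
gapless model is a deliberate scope restriction (all six rules are
positional over a fixed-length duplex) and bulged sites are not
searched.

```{r}
m <- "UGGAAGCUGGUCAUGAAUGGC"
site <- rev_comp(m)            # perfect site
d <- score_duplex(m, site)
d$mismatch_score
cat(render_alignment(d))
```

## The synthetic study and what it shows

`generate_truth_set()` builds a deterministic desk-scale study:
a 100-kb random genome carrying 30 canonical novel hairpins (24
expressed in both libraries, 3 private to each), 6 "known" miRNA loci
that back the miRBase-style reference, 10 decoys — two each of
no-duplex (shuffled star arm), 7 unpaired duplex nucleotides,
loop-spanning read, 260-nt separation, and 24-nt mature — plus ncRNA
genes (rRNA/tRNA/snoRNA/snRNA/siRNA), three exon–intron gene models,
and 40 transcripts with target sites designed to pass or fail one
named rule each. Seven hairpins carry miRNA* reads at under 10% of
their mature's count, echoing the rarity of star reads in real
libraries. Abundances follow a discretised log-normal (meanlog 3.5,
sdlog 1.2, clamped to [4, 3000]) — real libraries show counts spanning
from a handful to hundreds of thousands, and a log-normal is the
simplest shape with that skew. Reads are inserts plus the full 3'
adapter with Sanger qualities, uniform substitution errors at 0.2% per
base, deliberate singletons, and junk classes exercising every
cleaning filter. Each planted element is constructed so its criterion
verdict is forced (e.g. the unpaired-7 decoy uses a poly-A/poly-C
internal loop that cannot re-pair in any register), and the manifest
records every parameter and per-read truth.

Passing the end-to-end tests on this study shows that the pipeline
recovers exactly the planted signal under realistic skew and noise; it
does **not** show performance on real data, where hairpins are less
canonical, repeat-derived siRNAs are vastly more abundant, genomes are
orders of magnitude larger, and adapter chemistry is messier. The
generator also makes no attempt at realistic quality-score profiles or
indel errors.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally and in BED; GFF3 output
  is 1-based inclusive (stated in the file headers).
* N bases never pair and are excluded from composition; reads with N
  are dropped in cleaning (the perfect-match mapper has no wildcard).
* Adapter search: earliest exact occurrence of the 8-nt adapter
  prefix; reads without one are rescanned allowing one mismatch;
  reads with no located 3' adapter are dropped as contaminants.
* Tags with more than 20 genomic placements are set aside as
  repeat-derived and excluded from hairpin calling.
* `evaluate_candidate()` projects star ends through bulges via the
  nearest paired mature position; a read whose fold leaves it unpaired
  is rejected, not an error.
* All duplex comparisons (rule 6, strict bounds) are exact integer
  comparisons; MFEI comparisons use plain doubles with strict `>`.
* The problem sizes in the tests — 100-kb genome, ~15,000 reads per
  library, 20 miRNAs × 100 kb of transcript scan — were chosen as the
  scale at which every oracle (naive scan, exhaustive rescoring, full
  DP) can be recomputed exactly alongside the implementation.

## Known limitations

* Gapped/bulged target sites are out of scope (ungapped rule model).
* The mapper is exact-match only, as the classical pipeline specifies;
  sequencing errors therefore cost sensitivity rather than specificity.
* Novel-family grouping (seed identity + edit distance ≤ 2) is a
  documented convention, not a miRBase nomenclature assignment.
* The siRNA class needs a reference set; the fallback (perfect
  antisense duplex between two mapped tags) is deliberately minimal.
* The built-in folding model is a simplified thermodynamic model: good
  enough to rank hairpins and evaluate criteria, not a replacement for
  a full parameter set when absolute energies matter.
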