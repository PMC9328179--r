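# peroscan

Rule-based annotation of peroxisomal targeting signals (PTS) in plant
protein sequences.

Most peroxisomal matrix proteins are imported by one of two signals. The
**PTS1** is a C-terminal tripeptide recognized by the PEX5 receptor; its
plant consensus is `[SA][KR][LMI]>` (`>` marks the protein's end). The
**PTS2** is a degenerate N-terminal nonapeptide recognized by PEX7, with
consensus `[RK][LVIQ]x2[LVIHQ][LSGAK]x[HQ][LAF]`. A handful of proteins —
catalase being the canonical case — carry instead an *internal* PTS1-like
tripeptide a few residues upstream of the terminus (catalase: `QKL-10>`,
QKL followed by ten residues).

`peroscan` is for researchers building or comparing peroxisome proteome
catalogues (e.g. transferring an *Arabidopsis thaliana* reference catalogue
to a crop such as *Solanum lycopersicum*). It provides:

- **PTS1 classification.** Each position (-3, -2, -1) partitions the 20
  amino acids into *high-abundance* (canonical), *low-abundance*
  (demonstrated but rare, e.g. N at -2 as in `SNL>`) and *unproven*
  classes. A tripeptide is **canonical** (all high), **non-canonical**
  (exactly one low), or has *no obvious PTS* in three sub-categories:
  **i** (≥2 low, none unproven), **ii** (exactly one unproven), **iii**
  (≥2 unproven). The class table is config-overridable (JSON).
- **PTS2 scanning** over the N-terminal window (default 40 residues), in
  strict mode (all constrained consensus positions) or relaxed mode
  (anchor positions 1, 8, 9 only, with deviations reported — needed
  because functional domains such as `RTx5HL` break the strict consensus).
- **Internal PTS1 scanning** (catalase-type motifs, end offsets 1–50 by
  default).
- **Positional propensity tables** over nonapeptide sets: propensity of
  residue *r* at position *p* = 100 · count / n, with the publication-style
  printed form (values exact at two decimals printed in full, others
  truncated toward zero to three significant figures: 11/14 → 78.5).
- **Comparative catalogues**: per-species category tallies, truncated
  integer canonical percentages, shared/unique non-canonical tripeptide
  sets, no-obvious sub-category listings, ortholog-map orphans.
- **A synthetic proteome generator** with per-protein ground truth and an
  incidental-signal audit, so every stage is testable without downloads.

## Worked example

```r
library(peroscan)

classify_pts1(c("SKL", "SNL", "PML", "SAK", "VVA"))
#>   tripeptide class_m3 class_m2 class_m1          label low_position
#> 1        SKL     high     high     high      canonical           NA
#> 2        SNL     high      low     high  non_canonical           -2
#> 3        PML      low      low     high   no_obvious_i           NA
#> 4        SAK     high      low unproven  no_obvious_ii           NA
#> 5        VVA      low unproven unproven no_obvious_iii           NA
```

`SKL>` is the textbook canonical signal; `SNL>` carries one low-abundance
residue (N at -2) and is non-canonical; `PML>` has two low residues
(category i); in `SAK>` lysine has never been demonstrated at -1
(category ii); `VVA>` has two unproven residues (category iii).

A dual-signal protein (an N-terminal PTS2 *and* a canonical terminal
PTS1, like Arabidopsis LACS7) keeps both lines of evidence; PTS2 takes
precedence in the summary category:

```r
annotate_protein(paste0("MAERQAALLAHL", strrep("G", 50), "SKL"),
                 id = "LACS7_like")
#> Protein LACS7_like (65 aa): PTS2
#>   terminal tripeptide SKL> [canonical]
#>   PTS2 site(s): RQAALLAHL@4
#>   dual signal (PTS2 + terminal PTS1)
```

Propensity of each residue per nonapeptide position, over a set of PTS2
domains:

```r
pt <- compute_propensity(c("RLQPILSHL", "RLAVILGHL", "RIQPVLSHF",
                           "RQAPILAHL", "RTNVILSHL", "RVTPLLGHL"))
subset(pt$table, position %in% c(1, 9))
#>    position residue count propensity printed
#> 1         1       R     6  100.00000   100.0
#> 21        9       L     5   83.33333    83.3
#> 22        9       F     1   16.66667    16.6
```

Arginine at position 1 in all six domains gives propensity 100; leucine
dominates position 9. Whole-proteome runs go through `annotate_proteome()`
or `run_pipeline()` (FASTA in, annotation/propensity TSVs and a
comparative JSON+TSV report out); `inst/exec/peroscan` wraps the same
functions as a shell command with `annotate`, `propensity`, `compare`,
`simulate` and `run` subcommands.

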