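---
title: "Classifying peroxisomal targeting signals: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying peroxisomal targeting signals: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peroscan)
```

## The classification model

Peroxisomal matrix import uses two receptor systems. PEX5 binds a
C-terminal tripeptide (PTS1); PEX7 binds an N-terminal nonapeptide
(PTS2). Neither signal is a single sequence: both are families of related
motifs whose members differ widely in how often, and how reliably, they
have been observed in functional signals. `peroscan` encodes that
knowledge as small, explicit rule tables rather than as a trained scoring
model — the aim is transparent catalogue curation, not probabilistic
targeting prediction (which tools such as Plant PTS1Predictor already do).

### PTS1: per-position residue classes

At each of the positions -3, -2 and -1 of the terminal tripeptide, the 20
standard residues are partitioned into three classes:

* **high-abundance** — the consensus residues (`S/A`, `K/R`, `L/M/I`);
* **low-abundance** — residues demonstrated in functional PTS1s but rare
  (for example N at -2 in `SNL>`, P at -3 in `PKL>`, F at -1 in `SRF>`);
* **unproven** — everything else: never shown to support PTS1 import at
  that position.

A tripeptide's label is a total function of its three classes, applied in
order:

| rule | classes | label |
|------|---------|-------|
| 1 | three high | `canonical` |
| 2 | one low, two high | `non_canonical` |
| 3 | no unproven, ≥ 2 low | `no_obvious_i` |
| 4 | exactly one unproven | `no_obvious_ii` |
| 5 | ≥ 2 unproven | `no_obvious_iii` |

The five rules partition all 8,000 tripeptides; the canonical block is
the 2 × 2 × 3 = 12-member set `{S,A} × {K,R} × {L,M,I}`. The sub-category
ordering encodes decreasing plausibility of PTS1 function: category i
tripeptides combine individually demonstrated residues (and some, such as
`TNL>` and `SNV>`, are experimentally functional — the classifier reports
tripeptide *structure*, not functional status; users needing functional
overrides should keep their own lists), while categories ii and iii
contain residues never observed in a working signal.

The default table is not printed anywhere as an explicit set in the
catalogue literature; it is assembled so that every published example
tripeptide receives its published label. That reverse-engineering forces
each membership: `PKL>`/`TKL>` put P and T in low(-3); `QKF>`, `IFT>` and
`VVA>` (category listings) put Q, I and V there; `SNL>`, `ASL>`, `SYM>`,
`AHL>`, `SML>`, `SLM>`, `ATS>`, `HQV>`, `IFT>` fix N, S, Y, H, M, L, T, Q,
F at -2, and the `ATS>`/`SAK>` discussion ("threonine and alanine are of
non-canonical nature") adds A; `SRF>`, `AKV>`, `SRY>` fix F, V, Y at -1.
Because the typography marking unproven residues in the source catalogues
is not perfectly consistent (I at -3 appears both marked and unmarked),
the table is config-overridable: `read_pts1_classes()` accepts a JSON
file with the same structure, validated for class overlap. One knock-on
consequence worth knowing: Q at -3 is low-abundance, so the catalase
motif `QKL` is itself a *non-canonical* tripeptide — it still qualifies
as an internal PTS hit, which accepts canonical and non-canonical motifs.

Sequences are uppercased before lookup; non-standard letters (X, B, Z, U,
`*`) fall to the unproven class with a warning, so dirty proteome files
degrade a call to a no-obvious sub-category instead of crashing.

### PTS2: anchored degenerate matching

The published consensus `[RK][LVIQ]x2[LVIHQ][LSGAK]x[HQ][LAF]` is encoded
per position (3, 4 and 7 are wildcards). Two modes exist because observed
functional PTS2 domains violate the strict sets at interior positions
(threonine at position 2 in `RTx5HL`; serine/threonine at position 6):

* **strict** — every constrained position must conform;
* **relaxed** (default) — only the *anchor* positions must conform;
  non-conforming constrained positions are reported as deviations, so a
  call like `RTx5HL` is a match carrying the annotation "position 2: T".

The default anchors are {1, 8, 9}: position 1 (R/K) and position 8 (H/Q)
are invariant across the catalogued Arabidopsis and tomato domains
(propensity 100), and position 9 is the terminal L/I/F core of the motif.
Strict matches are by construction a subset of relaxed matches — a
property the test suite checks on random sequences.

PTS2 scanning covers start positions 1..`pts2_window` (default 40). The
literature says only "N-terminal portion"; 40 residues comfortably covers
every catalogued plant PTS2 start while keeping the incidental-match rate
low. Whole-sequence scanning (`allow_internal_pts2`) is off by default
and exists for the transthyretin-like-protein case of an internal PTS2;
internal matches never drive the summary category.

### Internal PTS1 motifs and the offset convention

Catalase-type signals are found by classifying every 3-mer whose end
offset lies in 1..50 (observed plant offsets: 3, 10, 13) and keeping
canonical/non-canonical motifs. The `"motif-N>"` notation is used loosely
in the literature, so the convention is a parameter: the default
(`"after"`) counts the residues C-terminal to the motif's last residue
(`QKL` + 10 residues = `QKL-10`); `"between"` counts one fewer. The
terminal tripeptide itself (offset 0) is never an internal hit.

### Summary category precedence

Per protein: `PTS2` if any non-internal PTS2 site matches; else
`PTS1_canonical`/`PTS1_noncanonical` from the terminal call; else
`internal_PTS` if any internal hit; else `none`. Dual-signal proteins
(PTS2 plus a canonical/non-canonical terminus, as in Arabidopsis LACS7)
keep all evidence and a `dual_signal` flag; PTS2 wins the summary. In the
comparative tallies the catalase-type proteins sit *inside* the
no-obvious count (their terminal tripeptide has no obvious PTS) and are
additionally broken out, which is what reconciles a "10 no-obvious"
count with a "7 without any PTS" count when 3 of the 10 are catalases.

## Propensity statistics

For a set of *n* nonapeptides, the propensity of residue *r* at position
*p* is 100 · count / *n* — a per-column composition percentage, computed
without alignment because the motif is gap-free and fixed-length. Full
precision is kept internally. The *printed* form follows the convention
of the published comparative tables: a value exact at two decimal places
(every count out of 16 is, since 100/16 = 6.25) is printed in full
(11/16 → 68.75); anything else is truncated toward zero to three
significant figures (11/14 → 78.571… → 78.5, 6/14 → 42.857… → 42.8 — a
truncation, not a rounding). A single published cell (12.75 for a
2-of-16 count) is inconsistent with every other cell and is treated as a
typo. Integer species-level percentages (share of canonical PTS1s) use
`floor()`, which is the only rule that reproduces the published pair
68 (74/108) and 56 (55/97 = 56.7) simultaneously.

Tie-breaks: residues with equal counts at a position are listed
alphabetically. Two-species report layouts pair rows rank-by-rank within
each position.

## The synthetic proteome generator

`gen_proteome()` emulates a catalogue-like proteome: i.i.d. background
sequences (uniform residue frequencies by default; a plant-like frequency
vector can be supplied) into which one signal per protein is embedded by
*overwriting* residues in place, keeping lengths fixed. The default mix
is the reference catalogue's composition — 74 canonical PTS1, 24
non-canonical PTS1, 19 PTS2, 3 catalase-type internal, 7 signal-free, of
127 — with lengths 100–600 aa, PTS2 starts 1–32 (inside the scan
window) and internal offset 10 (`QKL-10`). Canonical motifs are drawn
from the 12-member consensus set, non-canonical motifs from the 17
catalogued non-canonical tripeptides, PTS2 motifs as random strict
consensus instantiations.

Background sequence can create signals by chance (a random terminal
tripeptide is canonical with probability 12/8000; a relaxed PTS2 match
occurs per window position with probability 2/20 · 2/20 · 3/20 ≈ 0.15%).
Rather than rejection-sampling these away — which would bias composition
— the generator runs an audit pass with the package's own scanners and
records every *incidental* signal per protein. Recovery testing then
demands exact agreement between the annotator and the precedence rule
applied to embedded-plus-incidental evidence, and exact recall of every
embedded motif at its recorded position. A fixed seed makes the output
byte-identical, including the FASTA serialization.

What the generator does **not** emulate: real amino-acid composition
(unless supplied), domain structure, homology between the two "species",
signal-adjacent context preferences, or annotation noise. Passing the
recovery tests therefore demonstrates that the scanners implement their
rules exactly — not that the rules capture all real peroxisomal biology.

## Problem sizes and numerical choices

The test suite exercises: all 8,000 tripeptides against a brute-force
oracle; internal-scan and PTS2-scan equivalence against naive
sliding-window oracles on random 200–300-mers; partition/conservation
invariants on 1,000 random 50–300-mers; synthetic recovery at n = 1,000
proteins; and multinomial composition at n = 10,000 (within three
standard errors). Catalogue-scale tallies are checked on a deterministic
127-protein synthetic catalogue with the reference composition, which
reproduces the 108 = 74 + 24 + 10 PTS1 arithmetic and the 68% canonical
share. Floating-point comparisons in the propensity printing use an
absolute guard of 1e-9 on the "exact at two decimals" test; all other
arithmetic is integer.

## Known limitations

* The residue-class table is curation, not inference; transferring it to
  distant taxa means editing the JSON, not re-fitting anything.
* Relaxed PTS2 matching with anchors {1, 8, 9} is deliberately permissive
  at positions 2–7; on random sequence it fires in roughly 6% of
  40-residue windows, so PTS2 calls on arbitrary (non-curated) proteomes
  should be treated as candidate lists.
* The pipeline consumes a precomputed ortholog map; it performs no
  ortholog inference of its own.
* No targeting-strength scoring, no piggybacking inference, no receptor
  structural modelling.
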