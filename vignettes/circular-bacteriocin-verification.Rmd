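---
title: "Verifying head-to-tail circular bacteriocins: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying head-to-tail circular bacteriocins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circbact)
```

## The problem

Circular bacteriocins are ribosomally synthesized antimicrobial
peptides whose backbone is closed head-to-tail by an amide bond
between the first and last residue of the mature core. Genomically
they are recognizable as a precursor gene (leader + core) clustered
with a characteristic set of context genes — a SpoIIM/DUF95 membrane
protein, an ABC ATP-binding protein, a membrane transporter, and
sometimes an immunity gene. Biochemically, circularity leaves two
computable fingerprints in MS data:

1. the intact mass is one water (18.02 Da average) *below* the mass
   deduced from the linear core sequence, because the closing amide
   bond is a dehydration; and
2. a tryptic digest contains *junction-spanning* fragments whose
   sequence reads continuously across the former termini — fragments
   that simply cannot arise from the linear chain.

`circbact` implements both fingerprints, the cluster mining that
produces the candidate cores, and the split-intein-mediated-ligation
(SIML) construct design used to produce such peptides in vitro or in
recombinant *E. coli*.

## Mass model and its numerical choices

Masses are residue sums: linear peptides add one water for the
terminal H/OH, circular ones do not. Two deliberate numerical choices
matter for reproducing literature values at four decimals:

- the **proton mass is 1.007276 Da** (the mass of H⁺), not the atomic
  weight of hydrogen; using 1.00794 shifts MH⁺ by ~0.7 mDa and breaks
  four-decimal agreement;
- masses are carried at **full double precision** and rounded only at
  presentation.

Ambiguity codes (B, J, O, U, X, Z) are rejected rather than averaged:
every downstream comparison is an exact mass target, and an averaged
residue mass silently poisons it. Methionine oxidation (+15.994915 Da)
is the one built-in variable modification — it is ubiquitous in
purified samples and required to explain the Met-containing fragments
in the reference data — at most one per peptide by default.

Two scales coexist deliberately. High-resolution LC-MS/MS fragment
matching uses monoisotopic masses at ±20 ppm. Intact linear-mode
MALDI masses of 6–7 kDa peptides are centroid averages over the
isotope envelope with Dalton-scale calibration, so the intact
dehydration check uses **average masses and a ±1.5 Da tolerance**.
With the reference pair "deduced 6615.93 / observed 6598.93" the
arithmetic difference is 17.00 Da, not 18: the observed peak is the
*protonated* cyclic species, `linear − H₂O + H⁺` =
`6615.93 − 18.015 + 1.007 = 6598.92`, which this model matches to
0.01 Da. The often-quoted "18 Da difference" refers to the neutral
dehydration; the check models the measured ion. The second reference
pair (7105.42/7089.15) sits ~0.7 Da from the model value — within
linear-mode calibration drift and the 1.5 Da window.

## Circular digestion

Cleavage follows a rule table (default trypsin: after K/R unless the
next residue, wrapping circularly, is proline). The circular digest is
enumerated over the doubled sequence, restricted to fragments of at
most core length starting in the first copy; a fragment with
`start + length − 1 > n` wraps the junction and is flagged. A core
with no cleavage site is returned intact as a single undigestible,
junction-spanning record.

One boundary case is worth stating precisely: with at least one
cleavage site there is exactly one junction-spanning zero-missed
fragment **unless position n itself is a cleavage site** — then the
junction bond coincides with a cut and no fragment wraps. The test
suite asserts this corrected invariant, and checks the whole digest
against an independent brute force (linearize at every cleavage site,
digest linearly, map back, union) on hundreds of random peptides.

Semi-specific expansion (prefixes and suffixes of fully tryptic
fragments, minimum length 6) models the ragged single-tryptic-terminus
peptides that de novo sequencing recovers; it is on by default in
matching mode because the reference fragment set contains several such
species. The junction flag of a truncated fragment is recomputed from
its coordinates, never inherited — a suffix can lose the wrap.
Missed cleavages default to 2: the reference set contains a
one-missed-cleavage fragment (an internal K), and one extra level is
margin at negligible cost.

## Mining

Mining is a transparent homology-plus-architecture scan rather than a
wrapper around external servers: deterministic, offline, testable.

- **Precursor search.** Every 40–150-residue protein is aligned
  locally (Smith–Waterman, BLOSUM62, gap open 10 / extend 1) against a
  panel of mature circular cores. A hit needs ≥30% identity over ≥50%
  of the panel core. The core start is the first aligned precursor
  position, then boundaries snap to the family's terminal-residue rule
  (N-terminal L/V/W within ±3 of the aligned start; C-terminal W/Y/F
  at, or within 3 residues of, the precursor C-terminus). The snap
  rule is one defensible reading of leader-boundary assignment by
  homology; candidates that cannot be snapped are dropped under
  `strict_termini` (default) or kept low-confidence.
- **Role classification.** Annotation keywords (SpoIIM/DUF95,
  ABC/ATP-binding, immunity) dominate, because curated GenBank
  products are more reliable than heuristics. When the annotation is
  silent: Walker A (`[AG]xxxxGK[ST]`) plus a downstream Walker B marks
  ATP-binding proteins; Kyte–Doolittle hydropathy (window 19,
  threshold 1.6, segments spanning ≥17 residues, gaps <5 merged)
  counts transmembrane segments, separating membrane (≥2 TM, 100–250
  aa), SpoIIM/DUF95-like (≥4 TM, 150–400 aa, low confidence) and
  immunity candidates (≤150 aa, 1–2 TM). The more specific ≥4-TM rule
  is evaluated before the ≥2-TM rule, otherwise it could never fire.
- **Cluster calls.** One call per precursor, spanning all features
  within 6 kb; completeness counts the distinct context roles found
  (0–3). Closticin-type linear bacteriocins (≥40% local identity to a
  linear panel entry) are reported separately and never receive a
  cyclization claim — their maturation is unresolved and no circular
  evidence should be implied.

The bundled reference panel contains the public mature enterocin AS-48
core plus synthetic stand-ins (named `_synthetic`, in files named
accordingly) for the other family members, constructed to carry the
family's hallmark features and the published fragment constraints. The
panel is a plain FASTA and should be replaced with curated records for
production mining; every identity threshold is configurable.

## Evidence and verdicts

`assemble_evidence` is deliberately conservative:
`circular_supported` requires **both** the intact dehydration check
and at least one junction-spanning fragment match; an intact peak
matching the non-dehydrated linear [M+H]⁺ instead gives
`linear_only`; anything else is `insufficient`. Ambiguity is
preserved: one observed peak may support several peptides, ties are
reported, never silently resolved. Fragment charge states searched
default to {1, 2}; the doubly-protonated species is what
high-resolution detection tables list for peptides of this size.

## Construct design

A circular core opened at split position *k* (the core's own 1-based
numbering) yields the rotation starting at *k*; its last residue is
the core residue *k − 1*. The SIML fusion orders the parts
IntC + permuted core + IntN + SsrA tag, so intein trans-splicing
excises the flanks and religates the core's new termini into the
circle; the SsrA tag (canonical `AANDENYALAA`) marks unspliced
product for degradation and is removable. The intein pair is a
configuration input: the package ships clearly-labelled synthetic
placeholder sequences, because the real Npu DnaE sequences are not
printed in this package's sources and shipping an unverified "real"
sequence would be worse than an honest placeholder.

Reverse translation uses a bundled approximate *E. coli* K-12
codon-usage table (`max_frequency` deterministic; `weighted`
seed-reproducible); `translate(reverse_translate(p)) == p` holds for
both strategies and is property-tested. The expression cassette is
promoter + ATG + coding + TAA + terminator with the promoter and
terminator segments taken from the constant regions of the published
T7 PCR primers; linear PCR templates derive the forward primer as
promoter + ATG + first 24 coding nucleotides (an exact amplicon
prefix) and the reverse primer as the reverse complement of the last
24 coding nucleotides + TAA + terminator.

## Synthetic data: what it emulates, and what it does not

The generator builds clusters whose core is a seeded point-mutated
copy (default rate 0.15, termini preserved) of a panel core behind a
49-residue leader, flanked by context genes engineered to trip the
corresponding classifier rules, with random spacers; peak lists are
the digest's doubly-protonated m/z under Gaussian ppm error (default
5 ppm), an intact peak under 0.3 Da error, and uniform decoys
constrained to lie ≥50 ppm from every true peak. One integer seed
makes every artifact byte-reproducible (R's Mersenne–Twister, state
restored afterwards).

Passing the closed loop (generate → mine → digest → match → verdict)
therefore demonstrates internal consistency and noise robustness at
the stated noise levels — not performance on real data, which adds
isotope envelopes, chimeric spectra, intensity-dependent mass error,
co-eluting contaminants, and genuinely novel cores with <30% panel
identity that homology mining will miss by construction. The decoy
placement rule in particular makes the 95% verdict-recovery target a
statement about tolerance arithmetic, not about database-search FDR.

Problem sizes used by the test suite — 500 random peptides for the
digest oracle, 200 noisy plus 20 noise-free pipeline trials, 1,000
translation round trips — were chosen as the smallest sets that
exercise every code path with stable statistics.

## Known limitations

- No fragment-ion (b/y) scoring, isotope envelopes, FDR estimation or
  retention-time modelling: matching is targeted, mass-only.
- GenBank support is a minimal dialect (CDS features, simple and
  complement locations) sufficient for the records the package writes
  and typical bacterial annotations; join() locations are not parsed.
- The miner trades sensitivity for transparency; it is anchored to its
  reference panel and will not discover families with no panel
  homolog.
- Leader-boundary snapping is homology-guided, not mechanistic; for
  precursors whose true leader ends >3 residues from the best local
  alignment start it will misplace the boundary.
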