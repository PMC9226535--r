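---
title: "Classifying prokaryotic X-family DNA polymerases and their genomic context"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying prokaryotic X-family DNA polymerases and their genomic context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polxscan)
```

## The biological problem

X-family DNA polymerases (PolXs) are small repair polymerases built around
the Pol&beta;-like nucleotidyltransferase palm fold. Prokaryotic PolXs
typically carry five domains, N- to C-terminal: an 8 kDa (dRP-lyase)
domain, thumb, palm, fingers, and a PHP domain that acts as a
metal-dependent 3'-5' exonuclease. The palm holds a triad of acidic
residues (canonically three aspartates) that coordinate the two catalytic
metal ions; the fingers domain binds the incoming dNTP.

A substantial fraction of prokaryotic PolXs are *noncanonical*: they have
lost one or more of the acidic triad residues, often carry deletions in the
palm and fingers, and are believed to function as exonucleases rather than
polymerases. Because bacterial non-homologous end joining (NHEJ) uses a Ku
homolog plus the multidomain ligase LigD -- whose nuclease (phosphoesterase)
domain is sometimes absent -- the exonuclease activity of PolX is a
candidate substitute, and PolX genes are expected to co-occur with NHEJ
genes non-randomly.

`polxscan` implements the computational side of this analysis as a tested
pipeline: alignment-anchored classification, domain-length profiling,
genome-level NHEJ classification with co-occurrence statistics, operon
neighborhood extraction, and synthetic-data generators that plant a known
ground truth under every stage.

## Alignment anchoring

All residue-level analyses are expressed in *reference numbering* (human
Pol&beta; by default) and translated to alignment columns through an
anchor: residue *k* of the reference maps to the column holding the
reference row's (*k* &minus; `first_residue_number` + 1)-th non-gap
character. Columns are 0-based internally and printed 1-based. The package
never aligns; the reference row must already be present in the input
alignment (profile-align it in beforehand if missing).

A residue *range* maps to the full inclusive column interval between its
end residues, so *insertion columns* -- columns where the reference is
gapped -- count toward a subject's domain length. This is deliberate: the
fingers window spans only 43 reference residues, and real subject sequences
reach fingers lengths of 55+ only through insertions relative to the
reference.

## Catalytic-triad classification

A triad call reads the three triad columns for each sequence:

* **canonical** -- all three residues in {D, E}. Pure-glutamate triads are
  canonical ("aspartate or rarely glutamate"); AEE and ARE are altered
  despite containing glutamates, which forces this exact rule.
* **indeterminate** -- any position is a gap or 'X' and the triad is not
  canonical. A third class avoids inflating the altered census with
  sequences whose state is simply unknown.
* **altered** -- everything else.

The default triad positions, Pol&beta; D190/D192/D256, are configuration
rather than constants: they derive from the UniProt P06746 / PDB
active-site annotation of human Pol&beta; and sit inside the palm window
178&ndash;279, consistent with known altered-triad anchors (e.g. the
E199/E234 positions of the *D. radiodurans* enzyme map into altered-triad
columns). Override them via `triad_spec()` when anchoring on a different
reference.

## Domain windows and truncation

Default windows, in Pol&beta; numbering: palm 178&ndash;279, fingers
272&ndash;314. The two windows overlap; that is how the reference
annotation is printed, so the package implements it as printed -- palm +
fingers need not partition the protein. A domain's length is the number of
non-gap subject residues in the window's full column interval. Truncation
thresholds are strict: palm < 77, fingers < 55; a length of exactly 77/55
is not truncated. `double_truncated` is the conjunction. A Figure-style
fingers binning at < 35 residues can be obtained by setting
`fingers_truncation_threshold = 35`; the default keeps 55, which is the
published double-truncation rule.

Length summaries report mean, median and a 95% CI of the mean as mean
&plusmn; 1.96 &times; SD/&radic;n. The normal approximation is appropriate
at the collection sizes involved (thousands of sequences) and matches the
very tight published CIs.

## Motif profiling

`site_spec()` names single- or multi-column sites in reference numbering:
the dNTP-binding basic residue (Pol&beta; D276 equivalent; lysine in most
canonical prokaryotic PolXs), the dNTP-pairing asparagine (N279), the
steric gate (271&ndash;272), the GS cis-peptide motif (274&ndash;275), the
palm arginine R183, and the nine-residue PHP metal site (consensus
HHHEHHEDH), which has no Pol&beta; equivalent and must be supplied in the
coordinates of whatever reference carries it (the synthetic scaffold ships
its own). Site states read only the reference-residue columns; insertion
columns between them are ignored, so a state string's width always equals
the site width.

## Genome model and NHEJ classification

Gene tables arrive as TSV with precomputed role labels (the upstream
homology and conserved-domain searches are out of scope; the TSV schema is
the integration boundary). Coordinates are 1-based inclusive, GenBank
convention. The classifier rules:

* a *functional LigD* carries LIG and POL_DOM **in the same protein**;
  split LIG-only and POL_DOM-only proteins never qualify;
* `nhej_nuc` = Ku present and a LIG+POL_DOM+PE protein present;
* `nhej_no_nuc` = Ku present and a LIG+POL_DOM protein without PE;
* `none` otherwise (Ku alone or LigD alone is not an NHEJ pathway).

When both LigD variants occur, `nhej_nuc` wins: a genome possessing the
nuclease-bearing LigD has that activity available. A single protein
carrying KU together with LigD domains is permitted and contributes to
both conditions (no such architecture is described in real annotations;
permissive handling avoids silent data loss). Genomes with both canonical
and altered PolX genes get `polx_status = "both"`.

## Co-occurrence statistics

`build_contingency()` cross-classifies genomes (one genome, one count).
How dual-PolX genomes enter the table is genuinely unknowable from the
published analysis, so `both_policy` is explicit configuration:
`exclude` (default), `as_altered`, `as_canonical`, or `own_row`.

`pearson_chi_square()` is the classical Pearson test: expected counts from
the product of marginals, no Yates correction (a low-expected-count flag is
raised instead of silently switching tests), and the upper-tail probability
from `pchisq(lower.tail = FALSE)` -- which *is* the regularized upper
incomplete gamma function Q(df/2, x/2). `permutation_p()` is the
independent oracle: it rebuilds the paired label lists, shuffles one margin
with a seeded generator, and uses the add-one estimator
(1 + #{stat &ge; obs})/(n_perm + 1) so the p-value is never zero.

The test-calibration invariants (type-I error in [0.03, 0.07] at
&alpha; = 0.05 over 1000 null datasets; power &ge; 95% at &alpha; = 0.01
under a planted NHEJ|PolX dependence) are checked through
`simulate_genome_statuses()`, the status-assignment core that
`simulate_genomes()` itself calls. Realizing 1000 full gene tables would
multiply the test budget without changing what is verified. The null-world
margins (0.6/0.25/0.15 on both axes) were chosen once so that every
expected count at n = 500 is comfortably above 5, where the asymptotic
test is meant to be calibrated.

## Neighborhood extraction

`extract_neighborhood()` implements the operon rule: up to 5 gene
positions on each side of the focal PolX gene, accepting a candidate only
if it is co-directional with the focal gene and within 300 bp of the
previously accepted gene (or the focal gene at the first step).
Overlapping genes get distance 0 (tighter than any positive cutoff).
Upstream/downstream are positional along the replicon; co-directionality
makes the strand-relative distinction immaterial for accepted genes.

Whether the published "within 300 bp from each other" chains through
rejected genes is not stated, so both readings exist: `chain` (default;
the walk stops at the first rejection, the natural operon reading) and
`independent` (the walk continues; always a superset of `chain`). The
choice is recorded in the run summary. Replicons are linear; circular
wrap-around is a logged limitation. `brute_force_neighborhood()` is an
independent oracle that enumerates candidate accepted sets (prefixes for
`chain`, all subsets for `independent`) and returns the unique set
consistent with the acceptance predicate.

`family_frequency()` counts, per (taxon class, focal PolX class) cell, the
genomes whose neighborhood contains each Pfam family at least once (a
genome counts once per family). Cells with fewer than 4 genomes and
families below 10% frequency are dropped -- the published filters, exposed
as arguments. Denominators are per cell because canonical and altered
PolXs are tabulated separately.

## What the generators emulate -- and what they do not

`simulate_msa()` builds rows against a fixed 575-residue scaffold
(`fixture_reference()`; 575 echoes the observed median PolX length of
~573) numbered like Pol&beta;, with the palm/fingers windows, triad, motif
sites and a nine-residue PHP consensus at designated positions. Alignment
geometry mirrors real PolX alignments in two respects chosen once:

* every subject carries a fixed 21-column gap at reference residues
  225&ndash;245, so the subject palm baseline is 81 residues (the observed
  canonical palm mean is ~81, against the 102-residue reference window);
* a 17-column insertion block sits between reference residues 300 and 301,
  so the subject fingers baseline is 60 (&ge; 55, hence not truncated),
  and a 13&ndash;26-residue fingers deletion (the observed palm-deletion
  size range, applied to both domains) yields 34&ndash;47 (< 55,
  truncated).

Planted deletions are contiguous gap runs confined to sub-windows that
avoid every designated site, and background substitution (default rate
0.02) also avoids them, so planting is unambiguous and the recovery tests
can demand *exact* equality. Default planted fractions are the stated
world: `f_altered = 0.275` (the observed altered fraction), palm/fingers
deletion fractions 0.054 and 0.03 (approximately the observed truncated
fractions among all sequences). Motif states are planted per class at the
observed conservation levels (e.g. N279 92.87% in canonical rows; GS 42%
in altered rows; PHP consensus 88%/98%).

What a green recovery test does **not** establish: the generator performs
no realignment (deletions are gaps against the fixed scaffold), no
phylogenetic correlation between rows, no indel placement ambiguity, and
no misalignment noise. Real alignments can misplace window boundaries in
ways the generator cannot produce; column-mapping robustness to alignment
error is outside what these tests can show.

`simulate_genomes()` draws each genome's (PolX, NHEJ) status from a joint
distribution whose default reproduces the published marginals (72.8% no
NHEJ, 20.6% NHEJ+Nuc, 6.6% NHEJ&minus;Nuc) and per-group PolX conditionals
(10.3/3.0, 7.7/7.2, 43/5.9 percent canonical/altered), then realizes the
statuses exactly as role labels on a linear replicon (8&ndash;15 genes,
lengths 300&ndash;3000 bp, truncated-geometric gaps with mean ~120 bp
capped at 1000 bp so both sub-300 bp and larger gaps occur). Some
NHEJ-negative genomes receive decoys (Ku alone; split LIG / POL_DOM
proteins) that must still classify as `none`. NHEJ-positive genomes are
planted ~1.5 Mb larger (5.0 vs 3.5 Mb means, SD 0.4 Mb) so the
genome-length comparison has a recoverable planted shift. It does not
emulate operon structure beyond the single planted partner, multi-replicon
genomes, or taxonomic correlation of gene content.

## Numerical and degenerate-input choices

* Truncation and family-frequency filters use the comparison operators
  exactly as published (strict `<` for truncation, "less than four
  genomes" and "less than 10%" as strict exclusions).
* Census ties are broken lexicographically for deterministic output.
* Degenerate contingency tables (one row/column, or a zero marginal) are
  returned by `build_contingency()` with a warning but rejected by the
  tests of independence with a "degenerate-table" error.
* Empty classes produce `n = 0` summary rows with no percentages rather
  than being dropped.
* All randomness flows through explicit `seed` arguments.

## Known limitations

* The package consumes precomputed alignments and role labels; homology
  search, clustering, alignment, trimming and tree inference are out of
  scope by design.
* Circular replicons are treated as linear.
* Per-phylum chi-square tests carry no multiple-testing correction,
  mirroring the published analysis; interpret per-phylum p-values
  accordingly.
* The published headline counts (canonical/altered census and so on) can
  only be recomputed against the published supplementary alignment, which
  cannot be bundled; `analyze_polx_alignment()` is the one-call entry
  point for users who have downloaded it.
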