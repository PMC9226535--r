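# polxscan

Classification and genomic-context analysis of prokaryotic X-family DNA
polymerases (PolXs) in R.

## The problem

Prokaryotic PolXs are Polβ-like repair polymerases with five domains
(8 kDa dRP-lyase, thumb, palm, fingers, PHP exonuclease). The palm carries
a catalytic triad of acidic residues (canonically three aspartates) that
coordinates the two catalytic metals. A large group of *noncanonical*
PolXs has lost these residues — and often 13–26-residue stretches of the
palm and fingers — while keeping an intact PHP nuclease domain, and such
genomes are enriched for the bacterial non-homologous end-joining (NHEJ)
machinery (Ku + LigD).

`polxscan` is for comparative genomicists who have (a) a protein multiple
sequence alignment of PolXs containing a reference row (human Polβ
numbering by default) and/or (b) per-genome gene tables with precomputed
domain-role labels, and want the downstream analysis as tested,
reproducible code:

* **Alignment anchoring** — map reference residue numbers to alignment
  columns; residue *k* ↦ the column of the reference's
  (*k* − first + 1)-th non-gap character.
* **Triad classification** — canonical iff all three triad residues ∈
  {D, E}; indeterminate if gapped/ambiguous; altered otherwise; plus a
  census of altered variants.
* **Domain truncation** — palm (Polβ 178–279) and fingers (272–314)
  lengths as non-gap residues in the window's column interval
  (insertions included), truncation at palm < 77 / fingers < 55 (strict).
* **Motif profiling** — steric gate, GS cis-peptide motif, dNTP-binding
  residues, nine-residue PHP site (HHHEHHEDH consensus), with per-class
  conservation percentages.
* **NHEJ classification** — `nhej_nuc` / `nhej_no_nuc` / `none` from Ku
  and single-protein LIG+POL_DOM(±PE) LigD architectures.
* **Co-occurrence statistics** — Pearson χ² of independence
  (χ² = Σ(O−E)²/E, df = (r−1)(c−1)) with a seeded permutation oracle,
  enrichment and genome-length reports.
* **Operon neighborhoods** — co-directional genes within ±5 positions and
  ≤ 300 bp spacing, plus Pfam-family frequencies per taxonomic class with
  the ≥4-genome and ≥10% filters.
* **Synthetic generators** — alignments and genome tables with planted,
  exactly recoverable ground truth for every stage.

## Worked example

```r
library(polxscan)

# a synthetic alignment with known planted structure
sim <- simulate_msa(300, f_altered = 0.3, f_palm_deletion = 0.1,
                    f_fingers_deletion = 0.1, seed = 42)
fx  <- fixture_reference()
res <- analyze_polx_alignment(sim$msa, ref_id = fx$ref_id,
                              triad = fx$triad, sites = fx$sites)
str(res$counts)
#> List of 6
#>  $ n_sequences       : int 300
#>  $ n_canonical       : int 210
#>  $ n_altered         : int 90
#>  $ n_indeterminate   : int 0
#>  $ n_altered_variants: int 87
#>  $ n_double_truncated: int 2
```

300 planted sequences: exactly the planted 30% (90) come back altered,
spread over 87 distinct triad variants; two sequences drew both a palm and
a fingers deletion and are called double-truncated. Palm lengths summarize
to a mean of ~79.6 (baseline 81 minus the occasional planted deletion),
and the planted dNTP-site conservation is recovered:

```r
fr <- res$conservation$site_frequencies
fr[fr$site == "dntp_N" & fr$class == "canonical", ][1:2, ]
#>      site     class state   n percent
#> 12 dntp_N canonical     N 188    89.5
#> 13 dntp_N canonical     S  22    10.5
```

Genome side — classification, χ² co-occurrence and neighborhoods:

```r
gsim <- simulate_genomes(500, partner_probability = 0.8, seed = 42)
summ <- summarize_genomes(gsim$genes)
ct   <- build_contingency(summ)          # PolX status x NHEJ status
pearson_chi_square(ct)
#> Pearson chi-square: X2 = 56.8614, df = 4, p = 1.323e-11
#> warning: some expected counts < 5
as.numeric(permutation_p(ct, 20000, seed = 1))
#> [1] 4.99975e-05                        # floor of the add-one estimator

ff <- family_frequency(extract_all_neighborhoods(gsim$genes))
head(ff, 1)
#>      taxon_class focal_polx_class         pfam_family n_genomes_with_family
#> 1: Actinomycetia          altered LigD_operon_partner                     3
#>    n_genomes_in_class frequency
#> 1:                  4      0.75
```

The planted dependence between PolX and NHEJ status is detected
(analytic p ≈ 1.3e−11; the permutation p sits at the 1/(n_perm+1) floor,
consistent with it), and the planted co-directional operon partner ranks
first in every reported (class, PolX-type) cell.

Real data enter through `read_fasta_alignment()` (aligned FASTA) and
`load_gene_table()` (TSV with columns genome_id, replicon_id, start, end,
strand, protein_id, roles, pfam_families, taxon_class, taxon_phylum).
A command-line front end is installed at `exec/polx-scan`
(`polx-scan classify|nhej|cooccur|neighbors|simulate-msa|simulate-genomes`).

## Documentation

See the methods vignette (`vignettes/polx-classification.Rmd`) for the
model, the planted-world defaults and their provenance, numerical choices
and known limitations.
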