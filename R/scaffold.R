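# Fixed synthetic PolX scaffold used by simulate_msa() and the worked
# examples. The scaffold is numbered like human Pol beta so the package's
# default triad / window / site configuration applies to it directly, but
# it is a synthetic stand-in, not a real protein sequence.
#
# Layout (reference numbering):
#   lyase 1-90, thumb 91-177, palm 178-279, fingers 272-314 (overlapping
#   windows, mirroring the reference annotation), PHP 315-575.
#   Triad D190/D192/D256; palm_R R183; steric gate YF at 271-272; GS motif
#   at 274-275; basic dNTP residue K276; dNTP-pairing N279; nine PHP
#   metal-site positions carrying the HHHEHHEDH consensus.
#
# Alignment geometry emulated by simulate_msa():
#   - every subject row carries a fixed 21-column gap at reference residues
#     225-245 (the reference has a 21-residue insertion relative to typical
#     prokaryotic PolXs), so the subject palm baseline is 81 residues;
#   - a 17-column insertion block sits between reference residues 300 and
#     301 (reference gapped, subjects occupied), so the subject fingers
#     baseline is 43 + 17 = 60 residues;
#   - plantable deletions are contiguous gap runs confined to
#     residues 196-224 (palm) and residues 282-300 plus the insertion
#     block (fingers), well clear of the triad and motif sites.

#' Fixed synthetic reference scaffold
#'
#' Returns the versioned template sequence and scaffold geometry used by
#' \code{\link{simulate_msa}} and the documentation examples. The template
#' is 575 residues (echoing the observed PolX median length), carries an
#' all-aspartate triad, the canonical motif states and the HHHEHHEDH PHP
#' consensus at its nine designated PHP positions.
#'
#' @return list with elements \code{template} (character scalar, 575
#'   residues), \code{ref_id}, \code{length}, \code{domains},
#'   \code{triad} (a \code{\link{triad_spec}}), \code{windows} (a
#'   \code{\link{domain_windows}}), \code{sites} (a \code{\link{site_spec}}
#'   including \code{php_site}), \code{php_consensus}, and the alignment
#'   geometry fields \code{palm_common_gap}, \code{palm_deletion_region},
#'   \code{fingers_insertion_after}, \code{fingers_insertion_len},
#'   \code{fingers_deletion_region}.
#' @examples
#' fx <- fixture_reference()
#' nchar(fx$template)
#' @export
fixture_reference <- function() {
  len <- 575L
  php_site <- c(330L, 332L, 334L, 368L, 400L, 402L, 434L, 436L, 468L)
  php_consensus <- "HHHEHHEDH"
  # deterministic low-complexity background; designated sites overwritten
  base <- strsplit(paste(rep("AVLSGKTEQRFNPIHMYWCG", ceiling(len / 20)),
                         collapse = ""), "", fixed = TRUE)[[1L]][seq_len(len)]
  base[c(190L, 192L, 256L)] <- "D"
  base[183L] <- "R"
  base[271:272] <- c("Y", "F")
  base[274:275] <- c("G", "S")
  base[276L] <- "K"
  base[279L] <- "N"
  base[php_site] <- strsplit(php_consensus, "", fixed = TRUE)[[1L]]
  list(template = paste0(base, collapse = ""),
       ref_id = "ref_polbeta_like",
       length = len,
       domains = list(lyase = c(1L, 90L), thumb = c(91L, 177L),
                      palm = c(178L, 279L), fingers = c(272L, 314L),
                      php = c(315L, 575L)),
       triad = triad_spec(reference_id = "ref_polbeta_like",
                          residue_numbers = c(190L, 192L, 256L)),
       windows = domain_windows(),
       sites = site_spec(list(palm_R = 183L,
                              steric_gate = 271:272,
                              gs_motif = 274:275,
                              dntp_basic = 276L,
                              dntp_N = 279L,
                              php_site = php_site)),
       php_consensus = php_consensus,
       palm_common_gap = c(225L, 245L),
       palm_deletion_region = c(196L, 224L),
       fingers_insertion_after = 300L,
       fingers_insertion_len = 17L,
       fingers_deletion_region = c(282L, 300L))
}
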