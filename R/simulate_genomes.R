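# Synthetic genome-table generator with planted PolX x NHEJ statuses,
# planted operon partners, and planted genome-length shifts.

#' Default joint distribution of PolX status and NHEJ status
#'
#' The default planted joint distribution reproduces the marginals and
#' conditionals observed in real non-redundant bacterial genomes: 72.8
#' percent of genomes lack NHEJ, 20.6 percent are NHEJ+Nuc and 6.6 percent
#' NHEJ-Nuc; canonical / altered PolX conditional frequencies per NHEJ
#' group are 10.3 / 3.0, 7.7 / 7.2 and 43 / 5.9 percent respectively.
#'
#' @return 3 x 3 numeric matrix (rows: PolX none/canonical/altered; cols:
#'   NHEJ none/nhej_nuc/nhej_no_nuc) summing to 1.
#' @export
default_joint_probs <- function() {
  nhej <- c(none = 0.728, nhej_nuc = 0.206, nhej_no_nuc = 0.066)
  cond <- cbind(none = c(none = 1 - 0.103 - 0.030,
                         canonical = 0.103, altered = 0.030),
                nhej_nuc = c(1 - 0.077 - 0.072, 0.077, 0.072),
                nhej_no_nuc = c(1 - 0.430 - 0.059, 0.430, 0.059))
  P <- sweep(cond, 2L, nhej, `*`)
  P / sum(P)
}

#' Draw planted per-genome statuses
#'
#' The status-assignment core of \code{\link{simulate_genomes}}: samples
#' one (polx_status, nhej_status) pair per genome from a joint
#' distribution. Exposed separately so distributional checks (type-I error,
#' power) can run without realizing full gene tables.
#'
#' @param n_genomes number of genomes.
#' @param joint_probs non-negative matrix with PolX statuses as rownames
#'   (from none/canonical/altered/both) and NHEJ statuses as colnames
#'   (none/nhej_nuc/nhej_no_nuc); normalized internally.
#' @param seed integer seed (NULL leaves the RNG alone).
#' @return \code{data.table} with columns genome_id, polx_status,
#'   nhej_status.
#' @export
simulate_genome_statuses <- function(n_genomes,
                                     joint_probs = default_joint_probs(),
                                     seed = NULL) {
  stopifnot(n_genomes >= 1L)
  if (!is.null(seed)) set.seed(seed)
  P <- as.matrix(joint_probs)
  if (any(P < 0) || sum(P) <= 0)
    stop("joint_probs must be a non-negative matrix with positive sum")
  if (is.null(rownames(P))) rownames(P) <- c("none", "canonical", "altered")[seq_len(nrow(P))]
  if (is.null(colnames(P))) colnames(P) <- c("none", "nhej_nuc", "nhej_no_nuc")[seq_len(ncol(P))]
  stopifnot(all(rownames(P) %in% .POLX_LEVELS),
            all(colnames(P) %in% .NHEJ_LEVELS))
  P <- P / sum(P)
  cell <- sample.int(length(P), n_genomes, replace = TRUE,
                     prob = as.vector(P))
  ri <- (cell - 1L) %% nrow(P) + 1L
  ci <- (cell - 1L) %/% nrow(P) + 1L
  data.table::data.table(genome_id = sprintf("G%05d", seq_len(n_genomes)),
                         polx_status = rownames(P)[ri],
                         nhej_status = colnames(P)[ci])
}

.TAXON_MAP <- data.frame(
  taxon_class = c("Bacilli", "Clostridia", "Actinomycetia",
                  "Alphaproteobacteria", "Gammaproteobacteria",
                  "Deinococci", "Bacteroidia"),
  taxon_phylum = c("Firmicutes", "Firmicutes", "Actinobacteria",
                   "Proteobacteria", "Proteobacteria",
                   "Deinococcus-Thermus", "Bacteroidetes"),
  stringsAsFactors = FALSE)

#' Simulate genome gene tables with planted ground truth
#'
#' Draws per-genome (PolX, NHEJ) statuses from \code{joint_probs} and
#' realizes them exactly as role labels on a linear replicon of genes with
#' random lengths, strands and intergenic gaps (truncated-geometric, mean
#' ~\code{gap_mean} bp, capped at \code{gap_max} so both sub-300 bp and
#' larger gaps occur). NHEJ-positive genomes receive a Ku protein plus a
#' single LigD protein carrying LIG+POL_DOM (+PE for nhej_nuc); some
#' NHEJ-negative genomes receive decoys (Ku alone, or split LIG-only and
#' POL_DOM-only proteins) that must classify as 'none'. With probability
#' \code{partner_probability} each PolX gene gets a co-directional
#' planted-family partner gene within 300 bp. NHEJ-positive genomes are
#' planted with larger genome lengths. Deterministic under \code{seed}.
#'
#' @param n_genomes number of genomes (>= 1).
#' @param joint_probs joint status distribution (see
#'   \code{\link{default_joint_probs}}).
#' @param genes_per_genome_range inclusive range of genes per replicon.
#' @param gap_mean,gap_max intergenic gap distribution parameters (bp).
#' @param planted_partner_family Pfam family name of the planted operon
#'   partner.
#' @param partner_probability probability that a PolX gene receives the
#'   planted partner.
#' @param seed integer seed (NULL leaves the RNG alone).
#' @return list with \code{genes} (gene table, TSV schema plus
#'   genome_length and gene_index) and \code{truth} (\code{data.table}:
#'   genome_id, polx_status, nhej_status, partner_planted, partner_family,
#'   genome_length, taxon_class, taxon_phylum; \code{joint_probs}
#'   attached as attribute).
#' @export
simulate_genomes <- function(n_genomes,
                             joint_probs = default_joint_probs(),
                             genes_per_genome_range = c(8L, 15L),
                             gap_mean = 120, gap_max = 1000,
                             planted_partner_family = "LigD_operon_partner",
                             partner_probability = 0.6,
                             seed = NULL) {
  stopifnot(n_genomes >= 1L,
            genes_per_genome_range[1L] >= 6L,
            genes_per_genome_range[1L] <= genes_per_genome_range[2L],
            partner_probability >= 0, partner_probability <= 1)
  if (!is.null(seed)) set.seed(seed)
  statuses <- simulate_genome_statuses(n_genomes, joint_probs, seed = NULL)

  bg_pool <- c("ABC_tran", "HTH_1", "MFS_1", "GGDEF", "Response_reg",
               "Acetyltransf_1", "Radical_SAM", "Helicase_C", "Sigma70_r2",
               "TPR_1", "Peptidase_M23", "Glycos_transf_2")
  glen <- numeric(n_genomes)
  taxa <- .TAXON_MAP[sample.int(nrow(.TAXON_MAP), n_genomes, replace = TRUE), ]
  partner_planted <- logical(n_genomes)
  tables <- vector("list", n_genomes)

  for (g in seq_len(n_genomes)) {
    ps <- statuses$polx_status[g]
    ns <- statuses$nhej_status[g]
    n_genes <- sample(genes_per_genome_range[1L]:genes_per_genome_range[2L], 1L)
    lens <- sample(300:3000, n_genes, replace = TRUE)
    gaps <- pmin(stats::rgeom(n_genes, 1 / (gap_mean + 1)), gap_max)
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    roles <- rep("", n_genes)
    fams <- ifelse(stats::runif(n_genes) < 0.4,
                   bg_pool[sample.int(length(bg_pool), n_genes, replace = TRUE)],
                   "")

    # distinct gene slots for the role-bearing proteins
    n_special <- 2L + 2L * (ps == "both") + (ps %in% c("canonical", "altered")) + 2L
    slots <- sample.int(n_genes, min(n_special, n_genes))
    take <- local({ i <- 0L; function() { i <<- i + 1L; slots[i] } })

    if (ns == "nhej_nuc") {
      roles[take()] <- "KU"
      roles[take()] <- "LIG,POL_DOM,PE"
    } else if (ns == "nhej_no_nuc") {
      roles[take()] <- "KU"
      roles[take()] <- "LIG,POL_DOM"
    } else {
      u <- stats::runif(1L)
      if (u < 0.15) {
        roles[take()] <- "KU"                     # Ku alone: still no NHEJ
      } else if (u < 0.30) {
        roles[take()] <- "LIG"                    # split LigD domains:
        roles[take()] <- "POL_DOM"                # still no NHEJ
      }
    }
    polx_idx <- integer(0)
    if (ps == "canonical") {
      polx_idx <- take(); roles[polx_idx] <- "POLX_CANONICAL"
    } else if (ps == "altered") {
      polx_idx <- take(); roles[polx_idx] <- "POLX_ALTERED"
    } else if (ps == "both") {
      i1 <- take(); i2 <- take()
      roles[i1] <- "POLX_CANONICAL"; roles[i2] <- "POLX_ALTERED"
      polx_idx <- c(i1, i2)
    }
    # planted co-directional operon partner adjacent to the (first) PolX
    if (length(polx_idx) > 0L &&
        stats::runif(1L) < partner_probability) {
      pi <- polx_idx[1L]
      cand <- c(pi + 1L, pi - 1L)
      cand <- cand[cand >= 1L & cand <= n_genes & !(cand %in% slots)]
      if (length(cand) > 0L) {
        pa <- cand[1L]
        strand[pa] <- strand[pi]
        fams[pa] <- planted_partner_family
        gaps[max(pi, pa)] <- sample(0:300, 1L)  # gap before the later gene
        partner_planted[g] <- TRUE
      }
    }
    starts <- cumsum(gaps) + c(0L, cumsum(lens))[seq_len(n_genes)] + 1L
    ends <- starts + lens - 1L
    glen[g] <- max(5e5, round(stats::rnorm(
      1L, mean = if (ns == "none") 3.5e6 else 5e6, sd = 4e5)))
    tables[[g]] <- data.table::data.table(
      genome_id = statuses$genome_id[g],
      replicon_id = paste0(statuses$genome_id[g], "_chr"),
      start = starts, end = ends, strand = strand,
      protein_id = sprintf("%s_p%03d", statuses$genome_id[g],
                           seq_len(n_genes)),
      roles = roles, pfam_families = fams,
      taxon_class = taxa$taxon_class[g],
      taxon_phylum = taxa$taxon_phylum[g],
      genome_length = glen[g])
  }
  genes <- data.table::rbindlist(tables)
  .recompute_gene_index(genes)
  truth <- data.table::data.table(
    genome_id = statuses$genome_id,
    polx_status = statuses$polx_status,
    nhej_status = statuses$nhej_status,
    partner_planted = partner_planted,
    partner_family = planted_partner_family,
    genome_length = glen,
    taxon_class = taxa$taxon_class,
    taxon_phylum = taxa$taxon_phylum)
  data.table::setorder(truth, genome_id)
  data.table::setattr(truth, "joint_probs", as.matrix(joint_probs))
  list(genes = genes[], truth = truth)
}
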