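# Genome-level model: per-genome gene tables with precomputed domain-role
# labels, and the PolX / NHEJ status classifiers.
#
# Role vocabulary (comma-separated in the TSV 'roles' column):
#   POLX_CANONICAL, POLX_ALTERED  - PolX gene with canonical / altered triad
#   KU                            - Ku homolog
#   LIG, POL_DOM, PE              - LigD ligase, polymerase, phosphoesterase
#                                   (nuclease) domains
# Roles arrive precomputed (the upstream conserved-domain search is out of
# scope); the TSV schema is the integration boundary. Coordinates are
# 1-based inclusive, GenBank convention.

.ROLE_VOCAB <- c("POLX_CANONICAL", "POLX_ALTERED", "KU", "LIG", "POL_DOM", "PE")
.GENE_TABLE_COLS <- c("genome_id", "replicon_id", "start", "end", "strand",
                      "protein_id", "roles", "pfam_families",
                      "taxon_class", "taxon_phylum")

.split_tokens <- function(x) {
  out <- strsplit(x, ",", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

.has_role <- function(roles, role) {
  vapply(.split_tokens(roles), function(v) role %in% v, logical(1L))
}

.recompute_gene_index <- function(dt) {
  data.table::setorder(dt, genome_id, replicon_id, start, end)
  dt[, gene_index := seq_len(.N) - 1L, by = .(genome_id, replicon_id)]
  dt
}

#' Load a per-genome gene table
#'
#' Reads and validates the TSV gene-table contract. Required columns:
#' genome_id, replicon_id, start, end, strand, protein_id, roles,
#' pfam_families, taxon_class, taxon_phylum; an optional genome_length
#' column is carried through. roles and pfam_families are comma-separated
#' (empty allowed). gene_index is recomputed from coordinates (0-based
#' order by (start, end) within each replicon).
#'
#' @param path path to the TSV file.
#' @return \code{data.table} of validated gene records.
#' @export
load_gene_table <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", colClasses = list(
    character = intersect(.GENE_TABLE_COLS,
                          c("genome_id", "replicon_id", "strand", "protein_id",
                            "roles", "pfam_families", "taxon_class",
                            "taxon_phylum"))))
  validate_gene_table(dt)
}

#' Validate a gene table
#'
#' @param dt data.frame/data.table with the gene-table columns.
#' @return A validated \code{data.table} with recomputed \code{gene_index}.
#' @export
validate_gene_table <- function(dt) {
  dt <- data.table::as.data.table(dt)
  missing_cols <- setdiff(.GENE_TABLE_COLS, names(dt))
  if (length(missing_cols) > 0L)
    stop("validation error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  dt[, start := as.integer(start)]
  dt[, end := as.integer(end)]
  dt[, roles := ifelse(is.na(roles), "", roles)]
  dt[, pfam_families := ifelse(is.na(pfam_families), "", pfam_families)]
  bad <- which(dt$start < 1L)
  if (length(bad) > 0L)
    stop("validation error: start < 1 in row ", bad[1L])
  bad <- which(dt$end < dt$start)
  if (length(bad) > 0L)
    stop("validation error: end < start in row ", bad[1L],
         " (protein '", dt$protein_id[bad[1L]], "')")
  bad <- which(!dt$strand %in% c("+", "-"))
  if (length(bad) > 0L)
    stop("validation error: strand must be '+' or '-' in row ", bad[1L])
  toks <- unique(unlist(.split_tokens(dt$roles)))
  unknown <- setdiff(toks, .ROLE_VOCAB)
  if (length(unknown) > 0L) {
    bad <- which(vapply(.split_tokens(dt$roles),
                        function(v) any(v %in% unknown), logical(1L)))[1L]
    stop("validation error: unknown role token '", unknown[1L],
         "' in row ", bad)
  }
  .recompute_gene_index(dt)
  dt[]
}

#' Write a gene table TSV
#'
#' @param dt a gene table (as from \code{\link{load_gene_table}} or
#'   \code{\link{simulate_genomes}}).
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_gene_table <- function(dt, path) {
  data.table::fwrite(data.table::as.data.table(dt), path, sep = "\t")
  invisible(path)
}

#' Classify one genome's NHEJ status
#'
#' A functional LigD carries both ligase (LIG) and polymerase (POL_DOM)
#' domains in the same protein; its nuclease-bearing variant additionally
#' carries PE. A genome is \code{nhej_nuc} if it has Ku and a
#' LIG+POL_DOM+PE protein; else \code{nhej_no_nuc} if it has Ku and a
#' LIG+POL_DOM protein without PE; else \code{none} (Ku or LigD alone, or
#' neither; split LIG / POL_DOM proteins do not qualify). When both LigD
#' variants are present, nhej_nuc takes precedence.
#'
#' @param genes gene records of a single genome.
#' @return one of \code{"none"}, \code{"nhej_nuc"}, \code{"nhej_no_nuc"}.
#' @export
classify_nhej <- function(genes) {
  genes <- data.table::as.data.table(genes)
  if (nrow(genes) == 0L) return("none")
  if (length(unique(genes$genome_id)) > 1L)
    stop("classify_nhej expects records of a single genome")
  rl <- .split_tokens(genes$roles)
  has <- function(p, role) role %in% p
  lig <- vapply(rl, has, logical(1L), role = "LIG")
  pol <- vapply(rl, has, logical(1L), role = "POL_DOM")
  pe <- vapply(rl, has, logical(1L), role = "PE")
  ku <- any(vapply(rl, has, logical(1L), role = "KU"))
  ligd_nuc <- any(lig & pol & pe)
  ligd_no_nuc <- any(lig & pol & !pe)
  if (ku && ligd_nuc) "nhej_nuc"
  else if (ku && ligd_no_nuc) "nhej_no_nuc"
  else "none"
}

#' Classify one genome's PolX status
#'
#' @param genes gene records of a single genome.
#' @return one of \code{"none"}, \code{"canonical"}, \code{"altered"},
#'   \code{"both"}.
#' @export
classify_polx_status <- function(genes) {
  genes <- data.table::as.data.table(genes)
  if (nrow(genes) == 0L) return("none")
  if (length(unique(genes$genome_id)) > 1L)
    stop("classify_polx_status expects records of a single genome")
  can <- any(.has_role(genes$roles, "POLX_CANONICAL"))
  alt <- any(.has_role(genes$roles, "POLX_ALTERED"))
  if (can && alt) "both" else if (can) "canonical" else if (alt) "altered"
  else "none"
}

#' Summarize all genomes in a gene table
#'
#' One summary row per distinct genome_id, ordered by genome_id. A gene
#' carrying either PolX role counts once toward \code{n_polx_genes}.
#'
#' @param genes a gene table covering one or more genomes.
#' @return \code{data.table} with columns genome_id, polx_status,
#'   nhej_status, n_polx_genes, taxon_class, taxon_phylum (and
#'   genome_length when present in the input).
#' @export
summarize_genomes <- function(genes) {
  genes <- data.table::as.data.table(genes)
  has_len <- "genome_length" %in% names(genes)
  if (nrow(genes) == 0L) {
    out <- data.table::data.table(genome_id = character(0),
                                  polx_status = character(0),
                                  nhej_status = character(0),
                                  n_polx_genes = integer(0),
                                  taxon_class = character(0),
                                  taxon_phylum = character(0))
    if (has_len) out[, genome_length := numeric(0)]
    return(out)
  }
  one <- function(sd, gid) {
    sub <- data.table::copy(sd)[, genome_id := gid]
    row <- data.table::data.table(
      polx_status = classify_polx_status(sub),
      nhej_status = classify_nhej(sub),
      n_polx_genes = sum(.has_role(sub$roles, "POLX_CANONICAL") |
                           .has_role(sub$roles, "POLX_ALTERED")),
      taxon_class = sub$taxon_class[1L],
      taxon_phylum = sub$taxon_phylum[1L])
    if (has_len) row[, genome_length := sub$genome_length[1L]]
    row
  }
  out <- genes[, one(.SD, .BY$genome_id), by = genome_id]
  data.table::setorder(out, genome_id)
  out[]
}

#' Write a genome-summary TSV
#'
#' @param summaries a \code{\link{summarize_genomes}} result.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_genome_summary <- function(summaries, path) {
  data.table::fwrite(data.table::as.data.table(summaries), path, sep = "\t")
  invisible(path)
}
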