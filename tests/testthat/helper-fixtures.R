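# Shared in-code fixtures: tiny gene tables and random replicons.

.datatable.aware <- TRUE  # enable data.table [ syntax inside tests

# a linear replicon from gene lengths, intergenic gaps and strands
make_replicon <- function(lens, gaps, strands, roles = NULL, fams = NULL,
                          genome_id = "g1", replicon_id = "r1",
                          taxon_class = "TestClass",
                          taxon_phylum = "TestPhylum") {
  n <- length(lens)
  if (is.null(roles)) roles <- rep("", n)
  if (is.null(fams)) fams <- rep("", n)
  starts <- cumsum(gaps) + c(0L, cumsum(lens))[seq_len(n)] + 1L
  data.table::data.table(
    genome_id = genome_id, replicon_id = replicon_id,
    start = starts, end = starts + lens - 1L, strand = strands,
    protein_id = sprintf("%s_p%02d", genome_id, seq_len(n)),
    roles = roles, pfam_families = fams,
    taxon_class = taxon_class, taxon_phylum = taxon_phylum)
}

random_replicon <- function(n = NULL) {
  if (is.null(n)) n <- sample(3:30, 1L)
  g <- make_replicon(lens = sample(200:2500, n, replace = TRUE),
                     gaps = sample(0:600, n, replace = TRUE),
                     strands = sample(c("+", "-"), n, replace = TRUE))
  fi <- sample(n, 1L)
  g$roles[fi] <- sample(c("POLX_CANONICAL", "POLX_ALTERED"), 1L)
  list(genes = g, focal = fi)
}

# genome of simple role-carrying proteins (coordinates irrelevant to
# classification)
make_genome <- function(role_sets, genome_id = "g1") {
  make_replicon(lens = rep(900L, length(role_sets)),
                gaps = rep(100L, length(role_sets)),
                strands = rep("+", length(role_sets)),
                roles = vapply(role_sets, paste, character(1L),
                               collapse = ","),
                genome_id = genome_id)
}

# contingency table object directly from a counts matrix
as_contingency <- function(counts) {
  structure(list(row_labels = rownames(counts) %||% paste0("r", seq_len(nrow(counts))),
                 col_labels = colnames(counts) %||% paste0("c", seq_len(ncol(counts))),
                 counts = counts, n_total = sum(counts)),
            class = "polx_contingency")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
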