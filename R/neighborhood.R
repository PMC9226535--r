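# Operon-style neighborhood extraction around PolX genes and the
# Pfam-family frequency table with the class-size and frequency filters.
#
# The candidate window is positional: at most max_genes_each_side gene
# positions left (upstream) and right (downstream) of the focal gene along
# the replicon. A candidate is accepted iff it lies on the focal gene's
# strand (when require_codirectional) and its intergenic distance to the
# previously accepted gene (or to the focal gene for the first step) is at
# most max_intergenic_bp. Under chain_rule = "chain" the walk stops at the
# first rejection; under "independent" it continues past rejections.
# Intergenic distance between genes a (leftmost) and b is
# start(b) - end(a) - 1, floored at 0 for overlapping genes. Replicons are
# treated as linear (no circular wrap-around).

#' Neighborhood extraction parameters
#'
#' @param max_genes_each_side candidate window size per direction
#'   (default 5).
#' @param max_intergenic_bp maximum intergenic spacing in bp (default 300).
#' @param require_codirectional require the focal gene's strand
#'   (default TRUE).
#' @param chain_rule "chain" (stop at first rejection; operon-style
#'   contiguity, the default) or "independent" (continue past rejections).
#' @return An object of class \code{polx_neighborhood_spec}.
#' @export
neighborhood_spec <- function(max_genes_each_side = 5L,
                              max_intergenic_bp = 300L,
                              require_codirectional = TRUE,
                              chain_rule = c("chain", "independent")) {
  chain_rule <- match.arg(chain_rule)
  stopifnot(max_genes_each_side >= 0L, max_intergenic_bp >= 0L)
  structure(list(max_genes_each_side = as.integer(max_genes_each_side),
                 max_intergenic_bp = as.integer(max_intergenic_bp),
                 require_codirectional = isTRUE(require_codirectional),
                 chain_rule = chain_rule),
            class = "polx_neighborhood_spec")
}

.intergenic_bp <- function(left_end, right_start) {
  max(right_start - left_end - 1L, 0L)
}

.focal_polx_class <- function(roles) {
  if (.has_role(roles, "POLX_CANONICAL")) "canonical"
  else if (.has_role(roles, "POLX_ALTERED")) "altered"
  else stop("contract error: focal gene carries no PolX role")
}

.check_replicon <- function(genes) {
  genes <- data.table::as.data.table(genes)
  if (length(unique(genes$replicon_id)) > 1L)
    stop("genes must belong to a single replicon")
  if (is.unsorted(genes$start))
    stop("genes must be sorted by start coordinate")
  genes
}

.neighborhood_result <- function(genes, focal_index, accepted_idx) {
  accepted_idx <- sort(accepted_idx)
  structure(list(focal_protein_id = genes$protein_id[focal_index],
                 focal_polx_class = .focal_polx_class(genes$roles[focal_index]),
                 genome_id = genes$genome_id[focal_index],
                 taxon_class = genes$taxon_class[focal_index],
                 members = genes[accepted_idx]),
            class = "polx_neighborhood")
}

#' @export
print.polx_neighborhood <- function(x, ...) {
  cat("polx_neighborhood of ", x$focal_protein_id, " (",
      x$focal_polx_class, " PolX, genome ", x$genome_id, "): ",
      nrow(x$members), " member gene(s)\n", sep = "")
  invisible(x)
}

# directional walk; dir = +1 (downstream) or -1 (upstream)
.walk <- function(genes, focal_index, spec, dir) {
  accepted <- integer(0)
  prev <- focal_index
  focal_strand <- genes$strand[focal_index]
  for (step in seq_len(spec$max_genes_each_side)) {
    j <- focal_index + dir * step
    if (j < 1L || j > nrow(genes)) break
    strand_ok <- !spec$require_codirectional || genes$strand[j] == focal_strand
    gap <- if (dir > 0L) .intergenic_bp(genes$end[prev], genes$start[j])
           else .intergenic_bp(genes$end[j], genes$start[prev])
    ok <- strand_ok && gap <= spec$max_intergenic_bp
    if (ok) {
      accepted <- c(accepted, j)
      prev <- j
    } else if (spec$chain_rule == "chain") {
      break
    }
  }
  accepted
}

#' Extract the co-directional neighborhood of a PolX gene
#'
#' @param genes gene records of one replicon, sorted by start coordinate.
#' @param focal_index 1-based row index of the focal PolX gene in
#'   \code{genes}.
#' @param spec a \code{\link{neighborhood_spec}}.
#' @return An object of class \code{polx_neighborhood}: focal protein id and
#'   PolX class, genome id, taxon class, and the accepted member genes
#'   ordered by coordinate (the focal gene is never a member).
#' @export
extract_neighborhood <- function(genes, focal_index,
                                 spec = neighborhood_spec()) {
  genes <- .check_replicon(genes)
  stopifnot(focal_index >= 1L, focal_index <= nrow(genes))
  accepted <- c(.walk(genes, focal_index, spec, -1L),
                .walk(genes, focal_index, spec, +1L))
  .neighborhood_result(genes, focal_index, accepted)
}

#' Brute-force neighborhood oracle
#'
#' Independent re-implementation of \code{\link{extract_neighborhood}} by
#' exhaustive enumeration: for each direction it enumerates all candidate
#' accepted sets inside the positional window (prefixes under the chain
#' rule, all subsets under the independent rule) and returns the unique set
#' consistent with the acceptance predicate. Intended as a test oracle.
#'
#' @inheritParams extract_neighborhood
#' @return An object of class \code{polx_neighborhood}.
#' @export
brute_force_neighborhood <- function(genes, focal_index,
                                     spec = neighborhood_spec()) {
  genes <- .check_replicon(genes)
  stopifnot(focal_index >= 1L, focal_index <= nrow(genes))
  focal_strand <- genes$strand[focal_index]

  gap_to <- function(prev, j, dir) {
    if (dir > 0L) .intergenic_bp(genes$end[prev], genes$start[j])
    else .intergenic_bp(genes$end[j], genes$start[prev])
  }
  # acceptance predicate for offset o given the set S of accepted offsets
  cond <- function(offsets, S, o, dir) {
    j <- focal_index + dir * o
    inward <- S[S < o]
    prev <- if (length(inward) == 0L) focal_index
            else focal_index + dir * max(inward)
    strand_ok <- !spec$require_codirectional ||
      genes$strand[j] == focal_strand
    strand_ok && gap_to(prev, j, dir) <= spec$max_intergenic_bp
  }
  solve_dir <- function(dir) {
    m <- 0L
    while (m < spec$max_genes_each_side) {
      j <- focal_index + dir * (m + 1L)
      if (j < 1L || j > nrow(genes)) break
      m <- m + 1L
    }
    if (m == 0L) return(integer(0))
    offsets <- seq_len(m)
    if (spec$chain_rule == "chain") {
      # accepted set must be a prefix 1..k with cond true on it and false
      # at k+1 (offsets past the first rejection are unconstrained)
      for (k in 0:m) {
        S <- offsets[offsets <= k]
        consistent <- all(vapply(seq_len(min(k + 1L, m)), function(o)
          cond(offsets, S, o, dir) == (o <= k), logical(1L)))
        if (consistent) return(focal_index + dir * S)
      }
    } else {
      # independent rule: unique subset that is a fixpoint of the predicate
      for (mask in 0:(2^m - 1L)) {
        S <- offsets[bitwAnd(mask, 2^(offsets - 1L)) > 0L]
        consistent <- all(vapply(offsets, function(o)
          (o %in% S) == cond(offsets, S, o, dir), logical(1L)))
        if (consistent) return(focal_index + dir * S)
      }
    }
    stop("internal error: no consistent accepted set found")
  }
  accepted <- c(solve_dir(-1L), solve_dir(+1L))
  .neighborhood_result(genes, focal_index, accepted)
}

#' Extract neighborhoods for every PolX gene of a gene table
#'
#' Convenience wrapper: runs \code{\link{extract_neighborhood}} for each
#' gene carrying a PolX role, replicon by replicon.
#'
#' @param genes a full gene table.
#' @param spec a \code{\link{neighborhood_spec}}.
#' @return list of \code{polx_neighborhood} objects.
#' @export
extract_all_neighborhoods <- function(genes, spec = neighborhood_spec()) {
  genes <- data.table::as.data.table(genes)
  out <- list()
  for (key in split(seq_len(nrow(genes)),
                    paste(genes$genome_id, genes$replicon_id, sep = "\r"))) {
    sub <- genes[key]
    data.table::setorder(sub, start, end)
    focal <- which(.has_role(sub$roles, "POLX_CANONICAL") |
                     .has_role(sub$roles, "POLX_ALTERED"))
    for (fi in focal)
      out[[length(out) + 1L]] <- extract_neighborhood(sub, fi, spec)
  }
  out
}

#' Pfam family frequencies in PolX neighborhoods
#'
#' Per (taxon class, focal PolX class) cell: the fraction of genomes whose
#' neighborhood contains at least one gene of each Pfam family (a genome
#' counts once per family however many neighborhood genes carry it).
#' Cells with fewer than \code{min_genomes_per_class} genomes are dropped
#' entirely; families below \code{min_frequency} are dropped.
#'
#' @param results list of \code{polx_neighborhood} objects.
#' @param min_genomes_per_class minimum genomes per cell (default 4).
#' @param min_frequency minimum family frequency (default 0.10).
#' @return \code{data.table} with columns taxon_class, focal_polx_class,
#'   pfam_family, n_genomes_with_family, n_genomes_in_class, frequency;
#'   sorted by cell then descending frequency.
#' @export
family_frequency <- function(results, min_genomes_per_class = 4L,
                             min_frequency = 0.10) {
  empty <- data.table::data.table(taxon_class = character(0),
                                  focal_polx_class = character(0),
                                  pfam_family = character(0),
                                  n_genomes_with_family = integer(0),
                                  n_genomes_in_class = integer(0),
                                  frequency = numeric(0))
  if (length(results) == 0L) return(empty)
  cell <- data.table::rbindlist(lapply(results, function(r)
    data.table::data.table(taxon_class = r$taxon_class,
                           focal_polx_class = r$focal_polx_class,
                           genome_id = r$genome_id)))
  denom <- unique(cell)[, .(n_genomes_in_class = data.table::uniqueN(genome_id)),
                        by = .(taxon_class, focal_polx_class)]
  fam <- data.table::rbindlist(lapply(results, function(r) {
    fams <- unique(unlist(.split_tokens(r$members$pfam_families)))
    if (length(fams) == 0L) return(NULL)
    data.table::data.table(taxon_class = r$taxon_class,
                           focal_polx_class = r$focal_polx_class,
                           genome_id = r$genome_id, pfam_family = fams)
  }))
  if (is.null(fam) || nrow(fam) == 0L) return(empty)
  fam <- unique(fam)  # once per genome per cell per family
  num <- fam[, .(n_genomes_with_family = data.table::uniqueN(genome_id)),
             by = .(taxon_class, focal_polx_class, pfam_family)]
  out <- merge(num, denom, by = c("taxon_class", "focal_polx_class"))
  out <- out[n_genomes_in_class >= min_genomes_per_class]
  out[, frequency := n_genomes_with_family / n_genomes_in_class]
  out <- out[frequency >= min_frequency]
  data.table::setorder(out, taxon_class, focal_polx_class, -frequency,
                       pfam_family)
  out[]
}

#' Write neighborhood members to TSV
#'
#' One row per accepted member gene, annotated with the focal protein id
#' and focal PolX class.
#'
#' @param results list of \code{polx_neighborhood} objects.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_neighborhoods <- function(results, path) {
  rows <- data.table::rbindlist(lapply(results, function(r) {
    if (nrow(r$members) == 0L) return(NULL)
    dt <- data.table::copy(r$members)
    dt[, focal_protein_id := r$focal_protein_id]
    dt[, focal_polx_class := r$focal_polx_class]
    dt
  }), fill = TRUE)
  data.table::fwrite(rows, path, sep = "\t")
  invisible(path)
}
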