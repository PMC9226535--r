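# Contingency tables over genome summaries, Pearson's chi-square test of
# independence, a seeded permutation oracle, and the descriptive
# enrichment / genome-length reports.

.POLX_LEVELS <- c("none", "canonical", "altered", "both")
.NHEJ_LEVELS <- c("none", "nhej_nuc", "nhej_no_nuc")

#' Build a contingency table from genome summaries
#'
#' Cross-classifies genomes by two status variables; each genome contributes
#' exactly one count. Dual-PolX ('both') genomes are handled by
#' \code{both_policy}: excluded (default, one-genome-one-count semantics
#' without guessing), recoded as altered or canonical, or kept as their own
#' row.
#'
#' @param summaries a \code{\link{summarize_genomes}} result.
#' @param row_var,col_var summary columns to cross-classify (defaults
#'   polx_status x nhej_status).
#' @param both_policy one of "exclude", "as_altered", "as_canonical",
#'   "own_row".
#' @param drop_empty drop categories with zero marginal (flagged in the
#'   \code{dropped} attribute).
#' @return An object of class \code{polx_contingency}: list with
#'   \code{row_labels}, \code{col_labels}, \code{counts} (integer matrix)
#'   and \code{n_total}.
#' @export
build_contingency <- function(summaries,
                              row_var = "polx_status",
                              col_var = "nhej_status",
                              both_policy = c("exclude", "as_altered",
                                              "as_canonical", "own_row"),
                              drop_empty = TRUE) {
  both_policy <- match.arg(both_policy)
  summaries <- data.table::as.data.table(summaries)
  if (nrow(summaries) == 0L)
    stop("summaries must be non-empty")
  rows <- as.character(summaries[[row_var]])
  cols <- as.character(summaries[[col_var]])
  fix_both <- function(v) {
    if (both_policy == "exclude") v[v == "both"] <- NA_character_
    else if (both_policy == "as_altered") v[v == "both"] <- "altered"
    else if (both_policy == "as_canonical") v[v == "both"] <- "canonical"
    v
  }
  if (row_var == "polx_status") rows <- fix_both(rows)
  if (col_var == "polx_status") cols <- fix_both(cols)
  keep <- !is.na(rows) & !is.na(cols)
  rows <- rows[keep]; cols <- cols[keep]
  lv <- function(v, var) {
    base <- if (var == "polx_status") .POLX_LEVELS else
      if (var == "nhej_status") .NHEJ_LEVELS else sort(unique(v))
    c(intersect(base, unique(c(base, v))), setdiff(unique(v), base))
  }
  rl <- lv(rows, row_var); cl <- lv(cols, col_var)
  counts <- table(factor(rows, levels = rl), factor(cols, levels = cl))
  counts <- matrix(as.integer(counts), nrow = length(rl),
                   dimnames = list(rl, cl))
  dropped <- list(rows = character(0), cols = character(0))
  if (drop_empty) {
    rkeep <- rowSums(counts) > 0L
    ckeep <- colSums(counts) > 0L
    dropped <- list(rows = rownames(counts)[!rkeep],
                    cols = colnames(counts)[!ckeep])
    counts <- counts[rkeep, ckeep, drop = FALSE]
  }
  out <- structure(list(row_labels = rownames(counts),
                        col_labels = colnames(counts),
                        counts = counts,
                        n_total = sum(counts)),
                   class = "polx_contingency")
  attr(out, "dropped") <- dropped
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    warning("degenerate table: fewer than 2 rows or columns; ",
            "independence testing is not possible")
  out
}

#' @export
print.polx_contingency <- function(x, ...) {
  cat("polx_contingency (n = ", x$n_total, "):\n", sep = "")
  print(x$counts)
  invisible(x)
}

.check_testable <- function(table) {
  stopifnot(inherits(table, "polx_contingency"))
  counts <- table$counts
  if (nrow(counts) < 2L || ncol(counts) < 2L ||
      any(rowSums(counts) == 0L) || any(colSums(counts) == 0L))
    stop("degenerate-table error: need >= 2 rows and columns, ",
         "all marginals > 0")
  counts
}

#' Pearson chi-square test of independence
#'
#' Classical Pearson test without continuity correction: expected counts
#' \code{E[i,j] = row_i * col_j / n}, statistic \code{sum((O-E)^2/E)},
#' df \code{(r-1)(c-1)}, and the upper-tail chi-square probability (the
#' regularized upper incomplete gamma function). A low-expected-count
#' warning flag is set when any expected cell is below 5.
#'
#' @param table a \code{\link{build_contingency}} result.
#' @return An object of class \code{polx_chisq}: list with
#'   \code{statistic}, \code{df}, \code{p_value}, \code{expected},
#'   \code{low_expected_warning}.
#' @export
pearson_chi_square <- function(table) {
  counts <- .check_testable(table)
  n <- sum(counts)
  expected <- outer(rowSums(counts), colSums(counts)) / n
  statistic <- sum((counts - expected)^2 / expected)
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  structure(list(statistic = statistic,
                 df = df,
                 p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
                 expected = expected,
                 low_expected_warning = any(expected < 5)),
            class = "polx_chisq")
}

#' @export
print.polx_chisq <- function(x, ...) {
  cat(sprintf("Pearson chi-square: X2 = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  if (x$low_expected_warning)
    cat("warning: some expected counts < 5\n")
  invisible(x)
}

#' Monte-Carlo permutation p-value for independence
#'
#' Reconstructs the paired row/column label lists from the counts, shuffles
#' the column labels \code{n_perm} times with the seeded generator, and
#' returns the add-one estimator
#' \code{(1 + #(stat_perm >= stat_obs)) / (n_perm + 1)}.
#'
#' @param table a \code{\link{build_contingency}} result.
#' @param n_perm number of permutations (>= 1000).
#' @param seed integer seed for reproducibility (NULL leaves the RNG alone).
#' @return numeric p-value, with attributes \code{n_perm} and
#'   \code{statistic}.
#' @export
permutation_p <- function(table, n_perm = 20000L, seed = NULL) {
  counts <- .check_testable(table)
  if (n_perm < 1000L)
    stop("n_perm must be >= 1000")
  if (!is.null(seed)) set.seed(seed)
  r <- nrow(counts); cc <- ncol(counts); n <- sum(counts)
  # label index vectors, one entry per genome
  ri <- rep.int(rep(seq_len(r), cc), as.vector(counts))
  ci <- rep.int(rep(seq_len(cc), each = r), as.vector(counts))
  expected <- outer(rowSums(counts), colSums(counts)) / n
  ev <- as.vector(expected)
  stat_obs <- sum((as.vector(counts) - ev)^2 / ev)
  hits <- 0L
  base <- ri  # precomputed row index part of cell index
  for (b in seq_len(n_perm)) {
    cperm <- ci[sample.int(n)]
    obs <- tabulate(base + r * (cperm - 1L), nbins = r * cc)
    if (sum((obs - ev)^2 / ev) >= stat_obs) hits <- hits + 1L
  }
  p <- (1 + hits) / (n_perm + 1)
  attr(p, "n_perm") <- n_perm
  attr(p, "statistic") <- stat_obs
  p
}

#' Per-group NHEJ-by-PolX enrichment report
#'
#' For all genomes together and (optionally) per taxon group: within each
#' PolX-status group, the proportion of genomes with each NHEJ status.
#' Groups smaller than \code{min_group_size} genomes are suppressed.
#'
#' @param summaries a \code{\link{summarize_genomes}} result.
#' @param group_by optional summary column to stratify by (e.g.
#'   "taxon_phylum" or "taxon_class"); the pooled "all" stratum is always
#'   reported.
#' @param min_group_size minimum genomes per (stratum, PolX status) group.
#' @return \code{data.table} with columns group, polx_status, n_group,
#'   nhej_status, n, proportion.
#' @export
enrichment_report <- function(summaries, group_by = NULL,
                              min_group_size = 4L) {
  summaries <- data.table::as.data.table(summaries)
  strata <- list(all = rep(TRUE, nrow(summaries)))
  if (!is.null(group_by)) {
    for (g in sort(unique(summaries[[group_by]])))
      strata[[g]] <- summaries[[group_by]] == g
  }
  rows <- list()
  for (gname in names(strata)) {
    sub <- summaries[strata[[gname]]]
    for (ps in intersect(.POLX_LEVELS, unique(sub$polx_status))) {
      grp <- sub[sub$polx_status == ps]
      if (nrow(grp) < min_group_size) next
      for (ns in .NHEJ_LEVELS) {
        k <- sum(grp$nhej_status == ns)
        rows[[length(rows) + 1L]] <- data.table::data.table(
          group = gname, polx_status = ps, n_group = nrow(grp),
          nhej_status = ns, n = k, proportion = k / nrow(grp))
      }
    }
  }
  if (length(rows) == 0L)
    return(data.table::data.table(group = character(0),
                                  polx_status = character(0),
                                  n_group = integer(0),
                                  nhej_status = character(0),
                                  n = integer(0), proportion = numeric(0)))
  data.table::rbindlist(rows)
}

#' Genome length by NHEJ status and PolX presence
#'
#' Summarizes genome lengths per (nhej_status x PolX presence) cell; rows
#' with missing lengths are excluded with a message giving the count.
#'
#' @param summaries a \code{\link{summarize_genomes}} result carrying a
#'   \code{genome_length} column.
#' @return \code{data.table} with columns nhej_status, polx_present, n,
#'   mean_length, median_length.
#' @export
genome_length_comparison <- function(summaries) {
  summaries <- data.table::as.data.table(summaries)
  if (!"genome_length" %in% names(summaries))
    stop("summaries must carry a genome_length column")
  miss <- is.na(summaries$genome_length)
  if (any(miss))
    message(sum(miss), " genome(s) excluded for missing genome_length")
  sub <- summaries[!miss]
  if (nrow(sub) == 0L) {
    warning("all genome lengths missing; empty report")
    return(data.table::data.table(nhej_status = character(0),
                                  polx_present = logical(0), n = integer(0),
                                  mean_length = numeric(0),
                                  median_length = numeric(0)))
  }
  sub[, polx_present := polx_status != "none"]
  out <- sub[, .(n = .N, mean_length = mean(genome_length),
                 median_length = stats::median(genome_length)),
             by = .(nhej_status, polx_present)]
  data.table::setorder(out, nhej_status, polx_present)
  out[]
}
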