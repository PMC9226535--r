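# PolX feature calling: catalytic triad classification, palm/fingers domain
# length measurement with truncation flags, active-site motif profiling and
# per-class conservation summaries.
#
# Classification rule: a triad is canonical iff all three residues are
# acidic (D or E); indeterminate iff any position is a gap or 'X' and the
# triad is not canonical; altered otherwise. Pure-glutamate triads count as
# canonical ("aspartate or rarely glutamate"); AEE and ARE are altered.

#' Catalytic triad specification
#'
#' Three catalytic acidic positions in reference numbering. The default uses
#' human Pol beta numbering with the catalytic aspartates D190, D192 and
#' D256 (UniProt P06746 active-site annotation); all three lie inside the
#' palm window 178-279.
#'
#' @param reference_id reference sequence identifier the numbering refers to.
#' @param residue_numbers strictly increasing integer vector of length 3.
#' @return An object of class \code{polx_triad_spec}.
#' @export
triad_spec <- function(reference_id = "POLB_HUMAN",
                       residue_numbers = c(190L, 192L, 256L)) {
  residue_numbers <- as.integer(residue_numbers)
  if (length(residue_numbers) != 3L || any(diff(residue_numbers) <= 0L))
    stop("residue_numbers must be three strictly increasing integers")
  structure(list(reference_id = reference_id,
                 residue_numbers = residue_numbers),
            class = "polx_triad_spec")
}

.classify_triad <- function(triad) {
  chars <- strsplit(triad, "", fixed = TRUE)
  vapply(chars, function(ch) {
    if (all(ch %in% c("D", "E"))) "canonical"
    else if (any(ch %in% c("-", "X"))) "indeterminate"
    else "altered"
  }, character(1L))
}

#' Call catalytic triads for every aligned sequence
#'
#' Reads the three triad columns (via the anchor) for each sequence and
#' classifies the triad as canonical, altered or indeterminate.
#'
#' @param msa a \code{\link{polx_msa}}.
#' @param anchor a \code{\link{build_anchor}} result on \code{msa}.
#' @param spec a \code{\link{triad_spec}}.
#' @return \code{data.frame} with columns \code{seq_id}, \code{triad}
#'   (3-character state, gaps allowed) and \code{class}.
#' @export
call_triads <- function(msa, anchor, spec = triad_spec()) {
  stopifnot(inherits(spec, "polx_triad_spec"))
  cols <- anchor_column(anchor, spec$residue_numbers)
  m <- .msa_columns(msa, cols)
  triad <- paste0(m[, 1L], m[, 2L], m[, 3L])
  data.frame(seq_id = msa$ids, triad = triad,
             class = .classify_triad(triad),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Census of altered triad variants
#'
#' Counts distinct triad strings among altered calls, sorted by descending
#' count, ties broken lexicographically.
#'
#' @param calls a \code{\link{call_triads}} result.
#' @return \code{data.frame} with columns \code{triad}, \code{count}.
#' @export
triad_variant_census <- function(calls) {
  alt <- calls$triad[calls$class == "altered"]
  if (length(alt) == 0L)
    return(data.frame(triad = character(0), count = integer(0)))
  tab <- table(alt)
  out <- data.frame(triad = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$triad), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Palm and fingers window specification
#'
#' Defaults follow Pol beta numbering: palm 178-279, fingers 272-314
#' (the two windows overlap by design of the reference annotation), with
#' strict truncation thresholds palm < 77 and fingers < 55 residues.
#'
#' @param palm,fingers inclusive reference residue ranges, length-2 integer.
#' @param palm_truncation_threshold,fingers_truncation_threshold positive
#'   integers; a domain is truncated when its length is strictly below the
#'   threshold.
#' @return An object of class \code{polx_domain_windows}.
#' @export
domain_windows <- function(palm = c(178L, 279L), fingers = c(272L, 314L),
                           palm_truncation_threshold = 77L,
                           fingers_truncation_threshold = 55L) {
  stopifnot(length(palm) == 2L, length(fingers) == 2L,
            palm[1L] <= palm[2L], fingers[1L] <= fingers[2L],
            palm_truncation_threshold > 0L, fingers_truncation_threshold > 0L)
  structure(list(palm = as.integer(palm), fingers = as.integer(fingers),
                 palm_truncation_threshold = as.integer(palm_truncation_threshold),
                 fingers_truncation_threshold = as.integer(fingers_truncation_threshold)),
            class = "polx_domain_windows")
}

.window_lengths <- function(msa, anchor, range) {
  cols <- columns_for_range(anchor, range[1L], range[2L])
  # non-gap residues of the subject inside the whole column interval,
  # including insertion columns where the reference is gapped
  ungapped_length(substr(msa$seqs, cols["start"] + 1L, cols["end"] + 1L))
}

#' Measure palm and fingers domain lengths with truncation flags
#'
#' A domain length is the number of non-gap subject residues inside the
#' window's full alignment column interval (insertion columns included, so
#' subject insertions lengthen the domain). Truncation uses strict '<'.
#'
#' @param msa a \code{\link{polx_msa}}.
#' @param anchor a \code{\link{build_anchor}} result on \code{msa}.
#' @param windows a \code{\link{domain_windows}}.
#' @return \code{data.frame} with columns \code{seq_id}, \code{full_length},
#'   \code{palm_length}, \code{fingers_length}, \code{palm_truncated},
#'   \code{fingers_truncated}, \code{double_truncated}.
#' @export
measure_domains <- function(msa, anchor, windows = domain_windows()) {
  stopifnot(inherits(windows, "polx_domain_windows"))
  palm_length <- .window_lengths(msa, anchor, windows$palm)
  fingers_length <- .window_lengths(msa, anchor, windows$fingers)
  palm_truncated <- palm_length < windows$palm_truncation_threshold
  fingers_truncated <- fingers_length < windows$fingers_truncation_threshold
  data.frame(seq_id = msa$ids,
             full_length = ungapped_length(msa$seqs),
             palm_length = palm_length,
             fingers_length = fingers_length,
             palm_truncated = palm_truncated,
             fingers_truncated = fingers_truncated,
             double_truncated = palm_truncated & fingers_truncated,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Active-site site specification
#'
#' Named sites in reference (Pol beta) numbering. Single positions or runs
#' of consecutive reference residues; site states read only the
#' reference-residue columns (insertion columns between them are ignored).
#' \code{php_site} (the nine-residue PHP nuclease motif, consensus
#' HHHEHHEDH) has no Pol beta equivalent and must be supplied for the
#' alignment's own reference when wanted.
#'
#' @param sites named list of integer vectors of reference residue numbers.
#' @return An object of class \code{polx_site_spec}.
#' @export
site_spec <- function(sites = list(palm_R = 183L,
                                   steric_gate = 271:272,
                                   gs_motif = 274:275,
                                   dntp_basic = 276L,
                                   dntp_N = 279L)) {
  if (is.null(names(sites)) || any(names(sites) == ""))
    stop("all sites must be named")
  sites <- lapply(sites, as.integer)
  structure(list(sites = sites), class = "polx_site_spec")
}

#' Profile active-site motif states
#'
#' For each sequence and each named site, concatenates the subject's
#' characters at the site's reference-residue columns (gap-aware).
#'
#' @param msa a \code{\link{polx_msa}}.
#' @param anchor a \code{\link{build_anchor}} result on \code{msa}.
#' @param sites a \code{\link{site_spec}}.
#' @return \code{data.frame} with \code{seq_id} plus one character column per
#'   site; each state string's width equals the site width.
#' @export
profile_motifs <- function(msa, anchor, sites = site_spec()) {
  stopifnot(inherits(sites, "polx_site_spec"))
  out <- data.frame(seq_id = msa$ids, stringsAsFactors = FALSE,
                    row.names = NULL)
  for (nm in names(sites$sites)) {
    cols <- anchor_column(anchor, sites$sites[[nm]])
    m <- .msa_columns(msa, cols)
    out[[nm]] <- apply(m, 1L, paste0, collapse = "")
  }
  out
}

.length_summary_row <- function(x) {
  n <- length(x)
  if (n == 0L)
    return(list(n = 0L, mean = NA_real_, median = NA_real_,
                ci_lo = NA_real_, ci_hi = NA_real_))
  m <- mean(x)
  half <- if (n > 1L) 1.96 * stats::sd(x) / sqrt(n) else NA_real_
  list(n = n, mean = m, median = stats::median(x),
       ci_lo = m - half, ci_hi = m + half)
}

#' Per-class conservation and length summary
#'
#' For each site and triad class, tabulates the percentage of sequences
#' carrying each observed state; states containing gaps or 'X' are counted
#' like any other state (they stay in the denominator, reported under their
#' own state string). Also summarizes full/palm/fingers lengths per class
#' (mean, median, and a normal-approximation 95 percent CI of the mean).
#'
#' @param calls a \code{\link{call_triads}} result.
#' @param profiles a \code{\link{profile_motifs}} result (same seq_ids).
#' @param metrics a \code{\link{measure_domains}} result (same seq_ids).
#' @param classes triad classes to report (default canonical and altered).
#' @return list with \code{site_frequencies} (site, class, state, n, percent
#'   -- percent absent for empty classes) and \code{length_summary} (class,
#'   measure, n, mean, median, ci_lo, ci_hi).
#' @export
summarize_conservation <- function(calls, profiles, metrics,
                                   classes = c("canonical", "altered")) {
  if (!setequal(calls$seq_id, profiles$seq_id) ||
      !setequal(calls$seq_id, metrics$seq_id))
    stop("calls, profiles and metrics must share seq_ids")
  profiles <- profiles[match(calls$seq_id, profiles$seq_id), , drop = FALSE]
  metrics <- metrics[match(calls$seq_id, metrics$seq_id), , drop = FALSE]
  site_names <- setdiff(names(profiles), "seq_id")

  freq <- list()
  for (cl in classes) {
    sel <- calls$class == cl
    n_cl <- sum(sel)
    for (s in site_names) {
      if (n_cl == 0L) {
        freq[[length(freq) + 1L]] <- data.frame(
          site = s, class = cl, state = NA_character_, n = 0L,
          percent = NA_real_, stringsAsFactors = FALSE)
        next
      }
      tab <- table(profiles[[s]][sel])
      df <- data.frame(site = s, class = cl, state = names(tab),
                       n = as.integer(tab),
                       percent = 100 * as.integer(tab) / n_cl,
                       stringsAsFactors = FALSE)
      df <- df[order(-df$n, df$state), , drop = FALSE]
      freq[[length(freq) + 1L]] <- df
    }
  }
  site_frequencies <- do.call(rbind, c(freq, list(make.row.names = FALSE)))

  measures <- c("full_length", "palm_length", "fingers_length")
  len <- list()
  for (cl in classes) {
    sel <- calls$class == cl
    for (ms in measures) {
      row <- .length_summary_row(metrics[[ms]][sel])
      len[[length(len) + 1L]] <- data.frame(
        class = cl, measure = ms, n = row$n, mean = row$mean,
        median = row$median, ci_lo = row$ci_lo, ci_hi = row$ci_hi,
        stringsAsFactors = FALSE)
    }
  }
  length_summary <- do.call(rbind, c(len, list(make.row.names = FALSE)))

  list(site_frequencies = site_frequencies, length_summary = length_summary)
}
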