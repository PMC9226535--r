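# End-to-end alignment analysis and report writers.

#' Full alignment-based PolX analysis
#'
#' Runs the alignment pipeline in one call: anchor the reference row, call
#' catalytic triads, census altered variants, measure palm/fingers domains
#' with truncation flags, profile motif sites and summarize conservation
#' per class.
#'
#' @param msa a \code{\link{polx_msa}} or a path to an aligned FASTA file.
#' @param ref_id reference row identifier.
#' @param first_residue_number numbering of the reference's first non-gap
#'   residue.
#' @param triad a \code{\link{triad_spec}}.
#' @param windows a \code{\link{domain_windows}}.
#' @param sites a \code{\link{site_spec}}.
#' @param exclude_reference drop the reference row from calls, metrics and
#'   profiles before summarizing (default TRUE; the reference is an anchor,
#'   not a member of the collection).
#' @return list with \code{calls}, \code{census}, \code{metrics},
#'   \code{profiles}, \code{conservation} and \code{counts} (n_sequences,
#'   n_canonical, n_altered, n_indeterminate, n_altered_variants,
#'   n_double_truncated).
#' @export
analyze_polx_alignment <- function(msa, ref_id,
                                   first_residue_number = 1L,
                                   triad = triad_spec(),
                                   windows = domain_windows(),
                                   sites = site_spec(),
                                   exclude_reference = TRUE) {
  if (is.character(msa))
    msa <- read_fasta_alignment(msa)
  anchor <- build_anchor(msa, ref_id, first_residue_number)
  calls <- call_triads(msa, anchor, triad)
  metrics <- measure_domains(msa, anchor, windows)
  profiles <- profile_motifs(msa, anchor, sites)
  if (exclude_reference) {
    keep <- calls$seq_id != ref_id
    calls <- calls[keep, , drop = FALSE]
    metrics <- metrics[keep, , drop = FALSE]
    profiles <- profiles[keep, , drop = FALSE]
  }
  census <- triad_variant_census(calls)
  conservation <- summarize_conservation(calls, profiles, metrics)
  counts <- list(n_sequences = nrow(calls),
                 n_canonical = sum(calls$class == "canonical"),
                 n_altered = sum(calls$class == "altered"),
                 n_indeterminate = sum(calls$class == "indeterminate"),
                 n_altered_variants = nrow(census),
                 n_double_truncated = sum(metrics$double_truncated))
  list(calls = calls, census = census, metrics = metrics,
       profiles = profiles, conservation = conservation, counts = counts)
}

#' Write a JSON run summary
#'
#' Records counts, configuration echo and the seed alongside the TSV
#' reports so a run is reproducible from its outputs.
#'
#' @param summary named list (counts, config, seed, ...).
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_run_summary <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Write the alignment-analysis TSV reports
#'
#' @param analysis an \code{\link{analyze_polx_alignment}} result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_analysis_reports <- function(analysis, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(triad_calls = file.path(dir, "triad_calls.tsv"),
             triad_census = file.path(dir, "triad_census.tsv"),
             domain_metrics = file.path(dir, "domain_metrics.tsv"),
             motif_profiles = file.path(dir, "motif_profiles.tsv"),
             site_frequencies = file.path(dir, "site_frequencies.tsv"),
             length_summary = file.path(dir, "length_summary.tsv"))
  data.table::fwrite(analysis$calls, paths["triad_calls"], sep = "\t")
  data.table::fwrite(analysis$census, paths["triad_census"], sep = "\t")
  data.table::fwrite(analysis$metrics, paths["domain_metrics"], sep = "\t")
  data.table::fwrite(analysis$profiles, paths["motif_profiles"], sep = "\t")
  data.table::fwrite(analysis$conservation$site_frequencies,
                     paths["site_frequencies"], sep = "\t")
  data.table::fwrite(analysis$conservation$length_summary,
                     paths["length_summary"], sep = "\t")
  invisible(paths)
}
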