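# Synthetic alignment generator with planted ground truth.
#
# Rows are derived from the fixed scaffold (see fixture_reference()):
# triads, motif states and deletions are planted per row and recorded, the
# background is mutated away from all designated sites, and deletions are
# realized as gap runs against the fixed scaffold alignment (no
# realignment), so window arithmetic is exact.

.sample_states <- function(n, states, probs) {
  states[sample.int(length(states), n, replace = TRUE, prob = probs)]
}

.NONACIDIC <- c("A", "K", "R", "T", "V", "P", "G", "S", "N", "Q")

.plant_triads <- function(n, class) {
  out <- character(n)
  can <- class == "canonical"
  if (any(can)) {
    # D-biased acidic triads
    m <- matrix(.sample_states(3L * sum(can), c("D", "E"), c(0.85, 0.15)),
                ncol = 3L)
    out[can] <- paste0(m[, 1L], m[, 2L], m[, 3L])
  }
  if (any(!can)) {
    k <- sum(!can)
    draw_one <- function() {
      ch <- ifelse(stats::runif(3L) < 0.7,
                   .sample_states(3L, .NONACIDIC, rep(1, 10L)),
                   .sample_states(3L, c("D", "E"), c(0.7, 0.3)))
      if (all(ch %in% c("D", "E")))  # guarantee >=1 non-acidic residue
        ch[sample.int(3L, 1L)] <- .sample_states(1L, .NONACIDIC, rep(1, 10L))
      paste0(ch, collapse = "")
    }
    out[!can] <- vapply(seq_len(k), function(i) draw_one(), character(1L))
  }
  out
}

# per-class motif state planting; probabilities follow the conservation
# levels reported for real canonical / altered PolXs
.plant_motifs <- function(n, class) {
  can <- class == "canonical"
  nc <- sum(can); na <- sum(!can)
  out <- data.frame(palm_R = character(n), steric_gate = character(n),
                    gs_motif = character(n), dntp_basic = character(n),
                    dntp_N = character(n), php_site = character(n),
                    stringsAsFactors = FALSE)
  rnd_aa <- function(k) .sample_states(k, .POLX_AA20, rep(1, 20L))
  if (nc > 0L) {
    out$palm_R[can] <- "R"
    out$steric_gate[can] <- .sample_states(nc, c("YF", "HF", "SF"),
                                           c(0.543, 0.400, 0.057))
    out$gs_motif[can] <- .sample_states(nc, c("GS", "GN"), c(0.976, 0.024))
    out$dntp_basic[can] <- .sample_states(nc, c("K", "R", "E", "A", "P"),
                                          c(0.848, 0.068, 0.028, 0.028, 0.028))
    out$dntp_N[can] <- .sample_states(nc, c("N", "S"), c(0.9287, 0.0713))
    out$php_site[can] <- .sample_states(
      nc,
      c("HHHEHHEDH", "HHPERHEDQ", "HHRERHEDC", "QHHEHHEDH", "HHRERHEDM",
        "HHHERHEDH"),
      c(0.880, 0.027, 0.023, 0.013, 0.010, 0.047))
  }
  if (na > 0L) {
    out$palm_R[!can] <- .sample_states(na, c("R", "K", "Q", "T"),
                                       c(0.5, 0.2, 0.15, 0.15))
    out$steric_gate[!can] <- paste0(rnd_aa(na), rnd_aa(na))
    out$gs_motif[!can] <- .sample_states(na, c("GS", "GN", "AS", "AA"),
                                         c(0.42, 0.25, 0.18, 0.15))
    out$dntp_basic[!can] <- .sample_states(
      na, c("E", "A", "P", "K", "R", "S", "T", "G"),
      c(0.241, 0.215, 0.149, 0.076, 0.042, 0.093, 0.092, 0.092))
    out$dntp_N[!can] <- ifelse(stats::runif(na) < 0.97,
                               .sample_states(na, c("I", "L", "V", "F"),
                                              rep(1, 4L)),
                               "N")
    out$php_site[!can] <- .sample_states(na, c("HHHEHHEDH", "HHPERHEDQ"),
                                         c(0.98, 0.02))
  }
  out
}

#' Simulate a PolX alignment with planted ground truth
#'
#' Generates an alignment of \code{n_seqs} subject rows plus the ungapped
#' scaffold reference row. A fixed fraction of rows (rounded) receives an
#' altered catalytic triad with at least one non-acidic residue; the rest
#' receive D-biased acidic triads. Motif states are planted per class with
#' realistic conservation levels; palm and fingers deletions are planted as
#' contiguous gap runs inside designated sub-windows that avoid every
#' designated site, so the planted truth is unambiguous. Background
#' positions are substituted at \code{substitution_rate}, avoiding the
#' designated sites. Identical arguments and seed give identical output.
#'
#' @param n_seqs number of subject sequences (>= 1).
#' @param f_altered fraction of rows with an altered triad (default 0.275,
#'   the observed altered fraction).
#' @param f_palm_deletion,f_fingers_deletion per-row probabilities of a
#'   planted palm / fingers deletion.
#' @param deletion_length_range inclusive range of deletion lengths
#'   (default 13-26 residues, the observed palm deletion sizes).
#' @param substitution_rate per-position background substitution
#'   probability.
#' @param seed integer seed (NULL leaves the RNG alone).
#' @return list with \code{msa} (a \code{\link{polx_msa}}; reference row
#'   first) and \code{truth} (\code{data.table}, one row per sequence
#'   including the reference: seq_id, class, triad, palm_length,
#'   fingers_length, full_length, deletion bookkeeping and the planted
#'   motif states; the generator parameters are attached as the
#'   \code{params} attribute).
#' @export
simulate_msa <- function(n_seqs, f_altered = 0.275,
                         f_palm_deletion = 0.054,
                         f_fingers_deletion = 0.03,
                         deletion_length_range = c(13L, 26L),
                         substitution_rate = 0.02,
                         seed = NULL) {
  stopifnot(n_seqs >= 1L,
            f_altered >= 0, f_altered <= 1,
            f_palm_deletion >= 0, f_palm_deletion <= 1,
            f_fingers_deletion >= 0, f_fingers_deletion <= 1,
            length(deletion_length_range) == 2L,
            deletion_length_range[1L] >= 1L,
            deletion_length_range[1L] <= deletion_length_range[2L])
  if (!is.null(seed)) set.seed(seed)
  fx <- fixture_reference()
  ins_len <- fx$fingers_insertion_len
  ins_after <- fx$fingers_insertion_after
  n_col <- fx$length + ins_len
  col_of_res <- function(r) ifelse(r <= ins_after, r, r + ins_len)
  ins_cols <- (ins_after + 1L):(ins_after + ins_len)

  palm_region <- fx$palm_deletion_region
  palm_region_cols <- col_of_res(palm_region[1L]):col_of_res(palm_region[2L])
  fingers_region_cols <- c(col_of_res(fx$fingers_deletion_region[1L]):
                             col_of_res(fx$fingers_deletion_region[2L]),
                           ins_cols)
  fingers_region_cols <- sort(fingers_region_cols)
  dmin <- as.integer(deletion_length_range[1L])
  dmax <- as.integer(deletion_length_range[2L])
  if (dmax > length(palm_region_cols) || dmax > length(fingers_region_cols))
    stop("deletion longer than window: max deletion length ", dmax,
         " exceeds a deletion sub-window")

  tmpl <- strsplit(fx$template, "", fixed = TRUE)[[1L]]
  triad_res <- fx$triad$residue_numbers
  site_res <- unlist(fx$sites$sites, use.names = FALSE)
  designated_cols <- sort(unique(col_of_res(c(triad_res, site_res))))
  common_gap_cols <- col_of_res(fx$palm_common_gap[1L]):
    col_of_res(fx$palm_common_gap[2L])

  # planted classes: exactly round(f_altered * n) altered rows
  n_alt <- as.integer(round(f_altered * n_seqs))
  class <- rep("canonical", n_seqs)
  class[sample.int(n_seqs, n_alt)] <- "altered"
  triads <- .plant_triads(n_seqs, class)
  motifs <- .plant_motifs(n_seqs, class)
  palm_del <- stats::runif(n_seqs) < f_palm_deletion
  fingers_del <- stats::runif(n_seqs) < f_fingers_deletion
  palm_len0 <- diff(fx$windows$palm) + 1L -
    (fx$palm_common_gap[2L] - fx$palm_common_gap[1L] + 1L)   # 81
  fingers_len0 <- diff(fx$windows$fingers) + 1L + ins_len    # 60

  m <- matrix(rep(tmpl, each = n_seqs), nrow = n_seqs)
  full_mat <- matrix("", nrow = n_seqs, ncol = n_col)
  full_mat[, setdiff(seq_len(n_col), ins_cols)] <- m
  full_mat[, ins_cols] <- .sample_states(n_seqs * ins_len, .POLX_AA20,
                                         rep(1, 20L))
  # background substitutions away from designated sites
  bg_cols <- setdiff(seq_len(n_col), c(designated_cols, ins_cols))
  if (substitution_rate > 0) {
    hit <- matrix(stats::runif(n_seqs * length(bg_cols)) < substitution_rate,
                  nrow = n_seqs)
    idx <- which(hit)
    if (length(idx) > 0L) {
      sub_mat <- full_mat[, bg_cols, drop = FALSE]
      sub_mat[idx] <- .sample_states(length(idx), .POLX_AA20, rep(1, 20L))
      full_mat[, bg_cols] <- sub_mat
    }
  }
  # planted triads and motif states
  triad_cols <- col_of_res(triad_res)
  tr <- do.call(rbind, strsplit(triads, "", fixed = TRUE))
  full_mat[, triad_cols] <- tr
  for (nm in names(fx$sites$sites)) {
    cols <- col_of_res(fx$sites$sites[[nm]])
    st <- do.call(rbind, strsplit(motifs[[nm]], "", fixed = TRUE))
    full_mat[, cols] <- st
  }
  # shared reference-insertion gap in the palm window
  full_mat[, common_gap_cols] <- "-"
  # planted deletions as contiguous gap runs
  palm_L <- integer(n_seqs); fingers_L <- integer(n_seqs)
  for (i in which(palm_del)) {
    L <- if (dmin == dmax) dmin else sample(dmin:dmax, 1L)
    s <- sample.int(length(palm_region_cols) - L + 1L, 1L)
    full_mat[i, palm_region_cols[s:(s + L - 1L)]] <- "-"
    palm_L[i] <- L
  }
  for (i in which(fingers_del)) {
    L <- if (dmin == dmax) dmin else sample(dmin:dmax, 1L)
    s <- sample.int(length(fingers_region_cols) - L + 1L, 1L)
    full_mat[i, fingers_region_cols[s:(s + L - 1L)]] <- "-"
    fingers_L[i] <- L
  }

  subj_seqs <- apply(full_mat, 1L, paste0, collapse = "")
  ref_row <- character(n_col)
  ref_row[setdiff(seq_len(n_col), ins_cols)] <- tmpl
  ref_row[ins_cols] <- "-"
  seq_ids <- sprintf("seq%05d", seq_len(n_seqs))
  msa <- polx_msa(c(fx$ref_id, seq_ids),
                  c(paste0(ref_row, collapse = ""), subj_seqs))

  truth <- data.table::data.table(
    seq_id = c(fx$ref_id, seq_ids),
    class = c("canonical", class),
    triad = c("DDD", triads),
    palm_length = c(diff(fx$windows$palm) + 1L, palm_len0 - palm_L),
    fingers_length = c(diff(fx$windows$fingers) + 1L,
                       fingers_len0 - fingers_L),
    full_length = c(fx$length,
                    fx$length + ins_len -
                      (fx$palm_common_gap[2L] - fx$palm_common_gap[1L] + 1L) -
                      palm_L - fingers_L),
    palm_deleted = c(FALSE, palm_del),
    palm_deletion_len = c(0L, palm_L),
    fingers_deleted = c(FALSE, fingers_del),
    fingers_deletion_len = c(0L, fingers_L),
    palm_R = c("R", motifs$palm_R),
    steric_gate = c("YF", motifs$steric_gate),
    gs_motif = c("GS", motifs$gs_motif),
    dntp_basic = c("K", motifs$dntp_basic),
    dntp_N = c("N", motifs$dntp_N),
    php_site = c(fx$php_consensus, motifs$php_site))
  data.table::setattr(truth, "params",
                      list(n_seqs = n_seqs, f_altered = f_altered,
                           f_palm_deletion = f_palm_deletion,
                           f_fingers_deletion = f_fingers_deletion,
                           deletion_length_range = c(dmin, dmax),
                           substitution_rate = substitution_rate,
                           seed = seed))
  list(msa = msa, truth = truth)
}
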