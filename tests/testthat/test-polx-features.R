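# triad calling, domain measurement, motif profiling, conservation

# tiny hand-built alignment: reference "ref" ungapped, triad at residues
# 2, 4, 6 of a 9-residue reference
tiny_msa <- function(subject_rows) {
  polx_msa(c("ref", names(subject_rows)),
           c("ACDEFGHIK", unname(subject_rows)))
}
tiny_spec <- triad_spec("ref", c(2L, 4L, 6L))

test_that("call_triads classifies canonical, altered and indeterminate", {
  # triad letters sit at string positions 2, 4, 6
  msa <- tiny_msa(c(aee = "AALELEAIK",  # triad AEE -> altered
                    are = "AALRLEAIK",  # ARE -> altered (despite E)
                    ddd = "ADLDLDAIK",  # DDD -> canonical
                    eee = "AELELEAIK",  # EEE -> canonical (acidic)
                    gap = "ADLEL-AIK",  # DE- -> indeterminate
                    amb = "ADLXLDAIK")) # DXD -> indeterminate
  calls <- call_triads(msa, build_anchor(msa, "ref"), tiny_spec)
  got <- setNames(calls$class, calls$seq_id)
  expect_equal(got[["aee"]], "altered")
  expect_equal(got[["are"]], "altered")
  expect_equal(got[["ddd"]], "canonical")
  expect_equal(got[["eee"]], "canonical")
  expect_equal(got[["gap"]], "indeterminate")
  expect_equal(got[["amb"]], "indeterminate")
  expect_equal(calls$triad[calls$seq_id == "aee"], "AEE")
  expect_equal(calls$triad[calls$seq_id == "gap"], "DE-")
})

test_that("triad_variant_census counts altered variants with stable order", {
  calls <- data.frame(seq_id = c("a", "b", "c", "d", "e"),
                      triad = c("AEE", "AEE", "ARE", "DDD", "BEE"),
                      class = c("altered", "altered", "altered",
                                "canonical", "altered"))
  cen <- triad_variant_census(calls)
  expect_equal(cen$triad, c("AEE", "ARE", "BEE"))  # ties lexicographic
  expect_equal(cen$count, c(2L, 1L, 1L))
  expect_equal(sum(cen$count), sum(calls$class == "altered"))

  empty <- triad_variant_census(data.frame(seq_id = "a", triad = "DDD",
                                           class = "canonical"))
  expect_equal(nrow(empty), 0L)
})

test_that("measure_domains counts window residues and flags strictly", {
  # reference 10 residues; palm window = residues 2..8 (7 residues)
  msa <- polx_msa(c("ref", "full", "cut", "edge"),
                  c("ACDEFGHIKL",
                    "ACDEFGHIKL",   # no gaps: palm 7
                    "AC--FG--KL",   # 3 residues in window
                    "ACDEF---KL"))  # 4 residues in window
  a <- build_anchor(msa, "ref")
  w <- domain_windows(palm = c(2, 8), fingers = c(7, 9),
                      palm_truncation_threshold = 4,
                      fingers_truncation_threshold = 2)
  m <- measure_domains(msa, a, w)
  expect_equal(m$palm_length, c(7L, 7L, 3L, 4L))
  expect_equal(m$palm_truncated, c(FALSE, FALSE, TRUE, FALSE))
  # strict '<': length exactly at threshold is NOT truncated ('edge')
  expect_false(m$palm_truncated[m$seq_id == "edge"])
  expect_equal(m$double_truncated, m$palm_truncated & m$fingers_truncated)
  expect_true(all(m$palm_length <= m$full_length))
})

test_that("subject insertions inside the window lengthen the domain", {
  # reference gapped at columns 4-6: insertion columns between residues 3,4
  msa <- polx_msa(c("ref", "ins", "noins"),
                  c("ACD---EFG",
                    "ACDWWWEFG",
                    "ACD---EFG"))
  a <- build_anchor(msa, "ref")
  w <- domain_windows(palm = c(2, 5), fingers = c(2, 5),
                      palm_truncation_threshold = 1,
                      fingers_truncation_threshold = 1)
  m <- measure_domains(msa, a, w)
  expect_equal(m$palm_length[m$seq_id == "ins"], 7L)    # 4 ref + 3 inserted
  expect_equal(m$palm_length[m$seq_id == "noins"], 4L)
})

test_that("palm_length equals a brute-force count on random small MSAs", {
  set.seed(55)
  for (rep in 1:25) {
    ncol <- sample(20:60, 1L)
    nseq <- sample(2:20, 1L)
    rows <- vapply(seq_len(nseq), function(i)
      paste0(sample(c("A", "D", "E", "K", "-"), ncol, replace = TRUE,
                    prob = c(0.25, 0.2, 0.2, 0.2, 0.15)), collapse = ""),
      character(1L))
    ref <- paste0(sample(c("A", "C", "-"), ncol, replace = TRUE,
                         prob = c(0.45, 0.45, 0.1)), collapse = "")
    nres <- ungapped_length(ref)
    if (nres < 4L) next
    msa <- polx_msa(c("ref", sprintf("s%02d", seq_len(nseq))), c(ref, rows))
    a <- build_anchor(msa, "ref")
    lo <- sample(seq_len(nres - 1L), 1L)
    hi <- sample(lo:nres, 1L)
    w <- domain_windows(palm = c(lo, hi), fingers = c(lo, hi))
    m <- measure_domains(msa, a, w)
    # brute force: enumerate every column of the interval explicitly
    cols <- columns_for_range(a, lo, hi)
    mat <- do.call(rbind, strsplit(msa$seqs, "", fixed = TRUE))
    brute <- rowSums(mat[, (cols["start"] + 1L):(cols["end"] + 1L),
                         drop = FALSE] != "-")
    expect_equal(m$palm_length, unname(brute))
  }
})

test_that("profile_motifs reads reference-residue columns only", {
  # gs-like 2-residue site at residues 3,4 with an insertion column between
  msa <- polx_msa(c("ref", "q1", "q2"),
                  c("ACG-SFG",
                    "ACGWSFG",   # insertion residue W must be ignored
                    "AC--SFG"))  # gap at the site
  a <- build_anchor(msa, "ref")
  sp <- site_spec(list(gs = 3:4, single = 5L))
  prof <- profile_motifs(msa, a, sp)
  expect_equal(prof$gs, c("GS", "GS", "-S"))
  expect_equal(nchar(prof$gs), rep(2L, 3L))
  expect_equal(prof$single, c("F", "F", "F"))
})

test_that("summarize_conservation reports per-class state percentages", {
  n <- 10L
  calls <- data.frame(seq_id = sprintf("s%02d", 1:n),
                      triad = rep("DDD", n), class = rep("canonical", n))
  profiles <- data.frame(seq_id = calls$seq_id,
                         dntp_N = c(rep("N", 9), "S"))
  metrics <- data.frame(seq_id = calls$seq_id, full_length = rep(575L, n),
                        palm_length = rep(81L, n), fingers_length = rep(60L, n))
  cons <- summarize_conservation(calls, profiles, metrics)
  fr <- cons$site_frequencies
  expect_equal(fr$percent[fr$class == "canonical" & fr$state == "N"], 90)
  expect_equal(fr$percent[fr$class == "canonical" & fr$state == "S"], 10)
  # empty class reported with n = 0 and no percentage
  alt <- fr[fr$class == "altered", ]
  expect_true(all(alt$n == 0L))
  expect_true(all(is.na(alt$percent)))
  # length summary: normal-approximation CI collapses at zero variance
  ls <- cons$length_summary
  palm <- ls[ls$class == "canonical" & ls$measure == "palm_length", ]
  expect_equal(palm$mean, 81)
  expect_equal(palm$ci_lo, 81)
  expect_equal(palm$ci_hi, 81)
})

test_that("classes partition and calls are permutation invariant", {
  sim <- simulate_msa(120, f_altered = 0.4, f_palm_deletion = 0.3,
                      f_fingers_deletion = 0.3, seed = 9)
  a <- build_anchor(sim$msa, "ref_polbeta_like")
  calls <- call_triads(sim$msa, a)
  expect_equal(sum(calls$class == "canonical") +
                 sum(calls$class == "altered") +
                 sum(calls$class == "indeterminate"),
               length(sim$msa$ids))
  # shuffle record order: per-sequence results unchanged
  set.seed(1)
  perm <- sample(length(sim$msa$ids))
  msa2 <- polx_msa(sim$msa$ids[perm], sim$msa$seqs[perm])
  calls2 <- call_triads(msa2, build_anchor(msa2, "ref_polbeta_like"))
  merged <- merge(calls, calls2, by = "seq_id")
  expect_equal(merged$class.x, merged$class.y)
  expect_equal(merged$triad.x, merged$triad.y)
})

test_that("deleting residues inside the palm window never increases palm_length", {
  sim <- simulate_msa(30, f_altered = 0.2, f_palm_deletion = 0, seed = 21)
  a <- build_anchor(sim$msa, "ref_polbeta_like")
  base <- measure_domains(sim$msa, a)
  # knock out 10 residues inside each subject's palm window
  cols <- columns_for_range(a, 196, 205)
  seqs <- sim$msa$seqs
  substr(seqs, cols["start"] + 1L, cols["end"] + 1L) <-
    strrep("-", cols["end"] - cols["start"] + 1L)
  seqs[1] <- sim$msa$seqs[1]  # keep the reference intact
  msa2 <- polx_msa(sim$msa$ids, seqs)
  after <- measure_domains(msa2, build_anchor(msa2, "ref_polbeta_like"))
  expect_true(all(after$palm_length <= base$palm_length))
})
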