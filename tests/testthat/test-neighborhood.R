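# neighborhood extraction, brute-force oracle, family frequencies

test_that("extract_neighborhood enforces window, spacing and strand rules", {
  # focal + six co-directional downstream genes, all 100 bp gaps:
  # the 5-gene positional cap limits acceptance to 5
  g <- make_replicon(lens = rep(600L, 7), gaps = rep(100L, 7),
                     strands = rep("+", 7),
                     roles = c("POLX_CANONICAL", rep("", 6)))
  r <- extract_neighborhood(g, 1L)
  expect_equal(nrow(r$members), 5L)
  expect_equal(r$focal_polx_class, "canonical")
  expect_false(r$focal_protein_id %in% r$members$protein_id)

  # adjacent gene at a 400 bp gap: rejected, chain walk stops
  g2 <- make_replicon(lens = rep(600L, 4), gaps = c(0L, 400L, 50L, 50L),
                      strands = rep("+", 4),
                      roles = c("POLX_ALTERED", rep("", 3)))
  expect_equal(nrow(extract_neighborhood(g2, 1L)$members), 0L)

  # adjacent opposite-strand gene: rejected
  g3 <- make_replicon(lens = rep(600L, 3), gaps = c(0L, 50L, 50L),
                      strands = c("+", "-", "+"),
                      roles = c("POLX_CANONICAL", "", ""))
  expect_equal(nrow(extract_neighborhood(g3, 1L)$members), 0L)
  # ... unless co-directionality is waived
  sp_free <- neighborhood_spec(require_codirectional = FALSE)
  expect_equal(nrow(extract_neighborhood(g3, 1L, sp_free)$members), 2L)

  # overlapping co-directional gene: distance floored at 0, accepted
  g4 <- make_replicon(lens = c(600L, 600L), gaps = c(0L, 50L),
                      strands = c("+", "+"),
                      roles = c("POLX_CANONICAL", ""))
  g4$start[2] <- g4$end[1] - 100L  # overlap
  g4$end[2] <- g4$start[2] + 599L
  expect_equal(nrow(extract_neighborhood(g4, 1L)$members), 1L)

  # degenerate cases
  expect_equal(nrow(extract_neighborhood(
    g, 1L, neighborhood_spec(max_genes_each_side = 0L))$members), 0L)
  g_only <- g[1]
  expect_equal(nrow(extract_neighborhood(g_only, 1L)$members), 0L)
  g_bad <- data.table::copy(g); g_bad$roles[1] <- ""
  expect_error(extract_neighborhood(g_bad, 1L), "contract error")
})

test_that("chain vs independent: independent accepts a superset", {
  # an opposite-strand gene breaks the chain; a later co-directional gene
  # still within 300 bp of the focal is reachable only independently
  g <- make_replicon(lens = c(600L, 60L, 100L), gaps = c(0L, 40L, 40L),
                     strands = c("+", "-", "+"),
                     roles = c("POLX_CANONICAL", "", ""))
  # distance focal->gene3 = 40 + 60 + 40 = 140 <= 300
  chain <- extract_neighborhood(g, 1L, neighborhood_spec(chain_rule = "chain"))
  indep <- extract_neighborhood(g, 1L,
                                neighborhood_spec(chain_rule = "independent"))
  expect_equal(nrow(chain$members), 0L)
  expect_equal(indep$members$protein_id, "g1_p03")
  expect_true(all(chain$members$protein_id %in% indep$members$protein_id))

  set.seed(19)
  for (rep in 1:50) {
    rr <- random_replicon()
    ch <- extract_neighborhood(rr$genes, rr$focal,
                               neighborhood_spec(chain_rule = "chain"))
    ind <- extract_neighborhood(rr$genes, rr$focal,
                                neighborhood_spec(chain_rule = "independent"))
    expect_true(all(ch$members$protein_id %in% ind$members$protein_id))
  }
})

test_that("results are invariant to coordinate translation and id relabeling", {
  set.seed(23)
  for (rep in 1:20) {
    rr <- random_replicon()
    base <- extract_neighborhood(rr$genes, rr$focal)
    shifted <- data.table::copy(rr$genes)
    shifted$start <- shifted$start + 10000L
    shifted$end <- shifted$end + 10000L
    relabeled <- data.table::copy(shifted)
    relabeled$protein_id <- sprintf("new_%02d", seq_len(nrow(relabeled)))
    r2 <- extract_neighborhood(shifted, rr$focal)
    r3 <- extract_neighborhood(relabeled, rr$focal)
    expect_equal(r2$members$protein_id, base$members$protein_id)
    expect_equal(which(relabeled$protein_id %in% r3$members$protein_id),
                 which(shifted$protein_id %in% r2$members$protein_id))
  }
})

test_that("family_frequency applies the class-size and frequency filters", {
  mk_result <- function(genome, fams, class = "SmallClass",
                        focal_class = "canonical") {
    members <- make_replicon(lens = rep(500L, max(1L, length(fams))),
                             gaps = rep(50L, max(1L, length(fams))),
                             strands = rep("+", max(1L, length(fams))),
                             fams = if (length(fams)) fams else "",
                             genome_id = genome, taxon_class = class)
    if (length(fams) == 0L) members <- members[0]
    structure(list(focal_protein_id = paste0(genome, "_focal"),
                   focal_polx_class = focal_class, genome_id = genome,
                   taxon_class = class, members = members),
              class = "polx_neighborhood")
  }
  # class with 3 genomes: excluded entirely
  small <- lapply(sprintf("s%d", 1:3), mk_result, fams = "FamA")
  expect_equal(nrow(family_frequency(small)), 0L)

  # 20-genome class: FamB in 1 genome (5%) excluded; FamC passes;
  # FamD twice within one genome's neighborhood counts once
  big <- c(list(mk_result("b1", c("FamC", "FamD", "FamD"), class = "Big")),
           list(mk_result("b2", c("FamC", "FamD"), class = "Big")),
           lapply(sprintf("b%d", 3:19), mk_result, fams = "FamC",
                  class = "Big"),
           list(mk_result("b20", "FamB", class = "Big")))
  ff <- family_frequency(big)
  expect_false("FamB" %in% ff$pfam_family)
  expect_equal(ff$n_genomes_with_family[ff$pfam_family == "FamD"], 2L)
  expect_equal(ff$frequency[ff$pfam_family == "FamD"], 0.1)
  expect_equal(ff$n_genomes_in_class[ff$pfam_family == "FamC"], 20L)
  expect_equal(ff$frequency[ff$pfam_family == "FamC"], 19 / 20)

  # canonical and altered focal classes tabulated separately
  mixed <- c(lapply(sprintf("m%d", 1:4), mk_result, fams = "FamE",
                    class = "Mix", focal_class = "canonical"),
             lapply(sprintf("m%d", 5:8), mk_result, fams = "FamF",
                    class = "Mix", focal_class = "altered"))
  fm <- family_frequency(mixed)
  expect_equal(fm$pfam_family[fm$focal_polx_class == "canonical"], "FamE")
  expect_equal(fm$pfam_family[fm$focal_polx_class == "altered"], "FamF")
})
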