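small_cfg <- function(...) {
  sim_config(seed = 101, n_species = 6, n_novel = 1,
             gene_lengths = c(COL1A1 = 300L, ALB = 200L),
             target_site_coverage = 200L, n_blanks = 2, ...)
}

test_that("config validation rejects impossible parameters", {
  expect_error(sim_config(n_species = 1), "n_species")
  expect_error(sim_config(p_semitryptic = 1.5), "probabilities")
  expect_error(sim_config(divergence = -1), "divergence")
})

test_that("simulated databases parse unchanged and respect divergence limits", {
  cfg <- small_cfg()
  simdb <- simulate_database(cfg)
  expect_s3_class(simdb, "species_db")
  expect_equal(sum(!simdb$is_decoy), 6L)
  expect_named(attr(simdb, "heldout"), "Novel_01")
  # round-trip through the FASTA parser
  path <- withr::local_tempfile(fileext = ".fasta")
  write_database_fasta(simdb, path)
  db2 <- parse_database(path, gene_set = simdb$genes)
  expect_setequal(db2$species, simdb$species)
  expect_identical(db2$alignments, simdb$alignments)

  # zero divergence: all species identical, empty difference matrix
  flat <- simulate_database(sim_config(seed = 3, n_species = 4,
                                       divergence = 0, gap_rate = 0,
                                       missing_gene_rate = 0,
                                       gene_lengths = c(G1 = 100L)))
  expect_equal(nrow(build_difference_matrix(flat, build_global_index(flat))),
               0L)
})

test_that("pairwise differences match the substitution-model expectation", {
  # two species on one split: each tip branch carries `divergence` expected
  # substitutions per site; with uniform replacement over the other 19
  # amino acids, P(diff) = p1(1-p2) + p2(1-p1) + p1 p2 (18/19)
  L <- 4000L
  div <- 0.1
  cfg <- sim_config(seed = 8, n_species = 2, n_novel = 0, divergence = div,
                    gap_rate = 0, missing_gene_rate = 0,
                    gene_lengths = c(G1 = L))
  db <- simulate_database(cfg)
  d <- build_difference_matrix(db, build_global_index(db))
  p <- 1 - exp(-div)
  p_diff <- 2 * p * (1 - p) + p * p * 18 / 19
  expect_lt(abs(nrow(d) - L * p_diff), 4 * sqrt(L * p_diff * (1 - p_diff)))
})

test_that("in-silico digestion follows tryptic rules", {
  pool <- digest_in_silico(c(G = "AKRPCDEFGHKLMNPQR"), p_semitryptic = 0,
                           length_range = c(2L, 30L), missed_cleavages = 0L)
  # cleavage after K (pos 2) but not after R (followed by P); after K at 11
  expect_setequal(pool$peptide, c("AK", "RPCDEFGHK", "LMNPQR"))

  set.seed(2)
  seqs <- c(A = paste(sample(AA, 200, replace = TRUE), collapse = ""))
  full <- digest_in_silico(seqs, p_semitryptic = 0)
  # fully tryptic: every peptide ends at K/R (or the C-terminus) and is a
  # substring at its stated coordinates
  for (i in seq_len(nrow(full))) {
    expect_identical(full$peptide[i],
                     substr(seqs[[full$gene[i]]], full$start[i], full$end[i]))
  }
  ends <- substr(full$peptide, nchar(full$peptide), nchar(full$peptide))
  internal <- full$end < nchar(seqs[["A"]])
  expect_true(all(ends[internal] %in% c("K", "R")))
  expect_true(all(nchar(full$peptide) >= 7 & nchar(full$peptide) <= 30))

  semi <- digest_in_silico(seqs, p_semitryptic = 1)
  for (i in seq_len(nrow(semi))) {
    expect_identical(semi$peptide[i],
                     substr(seqs[[semi$gene[i]]], semi$start[i], semi$end[i]))
  }
})

test_that("simulated evidence is deterministic and round-trips the writers", {
  cfg <- small_cfg()
  simdb <- simulate_database(cfg)
  plan <- data.frame(raw_file = c("s1", "b1"),
                     true_species = c("Species_01", NA),
                     is_blank = c(FALSE, TRUE))
  s1 <- simulate_evidence(simdb, cfg, plan = plan)
  s2 <- simulate_evidence(simdb, cfg, plan = plan)
  expect_identical(s1$evidence, s2$evidence)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_evidence(s1$evidence, p1, "maxquant_evidence")
  write_evidence(s2$evidence, p2, "maxquant_evidence")
  expect_identical(readLines(p1), readLines(p2))
  s3 <- simulate_evidence(simdb, cfg, plan = plan, seed = 999)
  expect_false(identical(s1$evidence, s3$evidence))

  back <- read_evidence(p1, "maxquant_evidence")
  expect_equal(nrow(back), nrow(s1$evidence))
  expect_equal(sum(back$intensity), sum(s1$evidence$intensity))
})

test_that("sample peptides come from the true species and blanks are protease-pure", {
  cfg <- small_cfg()
  simdb <- simulate_database(cfg)
  plan <- data.frame(raw_file = c("s1", "b1"),
                     true_species = c("Species_02", NA),
                     is_blank = c(FALSE, TRUE))
  sim <- simulate_evidence(simdb, cfg, plan = plan)
  ev <- flag_contaminants(sim$evidence, synthetic_contaminants())

  # every non-protease sample peptide occurs in the true species
  seqs <- chartr("I", "L", unlist(lapply(simdb$alignments, function(a)
    gsub("-", "", a[["Species_02"]], fixed = TRUE))))
  blob <- paste(seqs, collapse = "#")
  smp <- ev[ev$raw_file == "s1" & !ev$is_protease]
  expect_true(all(vapply(smp$stripped_seq,
                         function(p) grepl(p, blob, fixed = TRUE), TRUE)))

  # realized relative protease intensity matches the configured value
  expect_lt(abs(relative_protease_intensity(ev, "s1") -
                cfg$protease_relative_intensity), 0.05)
  # blanks: all quantified intensity is protease
  expect_equal(relative_protease_intensity(ev, "b1"), 1)
  blank <- ev[ev$raw_file == "b1"]
  expect_true(all(blank$intensity[!blank$is_protease] == 0))
})

test_that("an unreachable coverage target warns and emits the maximum", {
  cfg <- small_cfg()
  cfg$target_site_coverage <- 100000L
  simdb <- simulate_database(cfg)
  plan <- data.frame(raw_file = "s1", true_species = "Species_01",
                     is_blank = FALSE)
  expect_warning(simulate_evidence(simdb, cfg, plan = plan),
                 "covered residues")
})
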