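test_that("relative protease intensity is the protease share of total signal", {
  ev <- make_evidence("f", c("PROTPEP", "SAMPLEPEP"), intensity = c(10, 90))
  ev$is_protease <- c(TRUE, FALSE)
  expect_equal(relative_protease_intensity(ev, "f"), 0.1)
  ev2 <- make_evidence("f", "SAMPLEPEP", intensity = 0)
  expect_equal(relative_protease_intensity(ev2, "f"), 0)
  ev3 <- make_evidence("f", "PROTPEP", intensity = 5)
  ev3$is_protease <- TRUE
  expect_equal(relative_protease_intensity(ev3, "f"), 1)
})

test_that("the blank cutoff is the linear-interpolation upper quartile", {
  expect_equal(protease_cutoff(c(0.5, 0.6, 0.7, 0.8)), 0.725)
  expect_equal(protease_cutoff(0.9), 0.9)
  expect_error(protease_cutoff(numeric(0)), "manual")
  expect_lt(0.01, protease_cutoff(c(0.5, 0.6, 0.7, 0.8)))  # sample passes
})

test_that("site count tallies sites matching the assigned species set", {
  db <- toy_db(list(G1 = c(A = "KKKK", B = "KKRR")))
  ref <- build_reference(db, max_missing = Inf, add_decoys = FALSE)
  ss <- data.table::data.table(
    raw_file = "f", site = c(1L, 2L, 3L, 3L, 4L),
    aa = c("K", "K", "K", "R", "W"), j_score = 1)
  expect_equal(site_count(ss, "A", ref), 3L)      # sites 1,2,3 match A
  expect_equal(site_count(ss, "B", ref), 3L)      # sites 1,2 and R at 3
  expect_equal(site_count(ss, c("A", "B"), ref), 3L)  # any-member rule
  expect_equal(site_count(ss[0], "A", ref), 0L)
  # site 4 observed only with a non-matching amino acid: not counted
  expect_false(4L %in% ss$site[ss$aa == "K"])
})

test_that("brute-force site count agrees on random toys", {
  set.seed(41)
  for (rep in 1:5) {
    db <- random_toy_db(n_species = 4, gap_prob = 0.2)
    ref <- build_reference(db, max_missing = Inf, add_decoys = FALSE)
    n <- 25
    ss <- data.table::data.table(
      raw_file = "f", site = sample(ref$index$L, n, replace = TRUE),
      aa = sample(AA, n, replace = TRUE), j_score = 1)
    sp <- sample(db$species, 2)
    chars <- global_char_matrix_for_test(normalize_il(db), ref$index)
    brute <- length(unique(ss$site[
      chars[ss$site, sp[1]] == ss$aa | chars[ss$site, sp[2]] == ss$aa]))
    expect_equal(site_count(ss, sp, ref), brute)
  }
})

test_that("q-values are decoy fractions down the coverage ranking, monotonized", {
  res <- data.frame(site_count = c(400, 300, 200, 100),
                    decoy_only = c(FALSE, FALSE, FALSE, TRUE))
  out <- compute_qvalues(res)
  expect_equal(out$q_raw, c(0, 0, 0, 0.25))
  expect_equal(out$q_value, c(0, 0, 0, 0.25))
  expect_equal(out$above_fdr_threshold, c(FALSE, FALSE, FALSE, TRUE))

  # no decoys anywhere: all q = 0
  none <- compute_qvalues(data.frame(site_count = 3:1, decoy_only = FALSE))
  expect_true(all(none$q_value == 0) && !any(none$above_fdr_threshold))

  # all decoys: q = 1 everywhere
  alld <- compute_qvalues(data.frame(site_count = 3:1, decoy_only = TRUE))
  expect_true(all(alld$q_value == 1))

  # monotonization: an early decoy followed by many targets is rescued
  mix <- compute_qvalues(data.frame(site_count = 10:1,
                                    decoy_only = c(F, T, rep(F, 8))))
  expect_true(all(diff(mix$q_value[order(-mix$site_count)]) >= 0))
  expect_equal(mix$q_value[2], 1 / 10)  # min over deeper ranks

  # tied site counts share the q of the worst rank in the tie
  tie <- compute_qvalues(data.frame(site_count = c(5, 5, 5, 1),
                                    decoy_only = c(FALSE, TRUE, FALSE, TRUE)))
  expect_equal(tie$q_value, c(rep(1 / 3, 3), 1 / 2))
})

test_that("the empirical decoy fraction among accepted files respects the cutoff", {
  set.seed(43)
  for (rep in 1:20) {
    n <- 50
    res <- data.frame(site_count = sample(1000, n),
                      decoy_only = runif(n) < 0.2)
    out <- compute_qvalues(res, q_threshold = 0.01)
    acc <- !out$above_fdr_threshold
    if (any(acc)) expect_lte(mean(out$decoy_only[acc]), 0.01)
  }
})

test_that("the consensus takes the top-J amino acid with alphabetical ties", {
  ss <- data.table::data.table(
    raw_file = "f",
    site = c(1L, 1L, 2L, 3L, 3L),
    aa = c("A", "C", "W", "T", "G"),
    j_score = c(1, 0.0625, 1, 0.5, 0.5))
  cons <- consensus_sequence(ss, "f")
  expect_equal(cons$aa, c("A", "W", "G"))  # site 3 tie -> alphabetical
  expect_equal(nrow(consensus_sequence(ss[0], "f")), 0L)
})

test_that("deamidation fractions count annotated N/Q occurrences", {
  ev <- data.table::data.table(
    raw_file = "f",
    stripped_seq = c("ANNAK", "ANNAK", "PEPK"),
    modified_seq = c("_AN(de)NAK_", "_ANNAK_", "_PEPK_"),
    charge = 2L, intensity = 1, score = 50, precursor_q = NA_real_,
    is_protease = FALSE, is_contaminant = FALSE)
  fr <- deamidation_fractions(ev, "f")
  expect_equal(unname(fr["N"]), 0.25)  # 1 of 4 N occurrences
  expect_true(is.na(fr["Q"]))          # no Q anywhere
  ev$modified_seq <- gsub("(de)", "[Deamidated (NQ)]", ev$modified_seq,
                          fixed = TRUE)
  expect_equal(unname(deamidation_fractions(ev, "f")["N"]), 0.25)
  ev$modified_seq <- c("_ANNAK_", "_ANNAK_", "_PEPK_")
  expect_equal(unname(deamidation_fractions(ev, "f")["N"]), 0)
})
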