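test_that("pseudo-UniProt and UniProt headers are parsed into species/gene/taxon", {
  fasta <- c(
    ">NCBI | XP_1 | XP_1_COL1A1 collagen alpha-1 OS = Bos taurus OX = 9913 GN = COL1A1",
    "GPAGPR",
    ">sp|P02453|CO1A1_SHEEP Collagen alpha-1(I) OS=Ovis aries OX=9940 GN=COL1A1",
    "GPAGPK")
  db <- parse_database(fasta, gene_set = "COL1A1")
  expect_setequal(db$species, c("Bos taurus", "Ovis aries"))
  expect_equal(unname(db$taxa["Bos taurus"]), 9913L)
  expect_equal(names(db$alignments), "COL1A1")
  expect_equal(unname(db$alignments$COL1A1[["Bos taurus"]]), "GPAGPR")

  expect_equal(length(parse_database(character(0), gene_set = "COL1A1")$species), 0L)
})

test_that("records lacking tags or with unknown genes are rejected with warnings", {
  fasta <- c(">no tags here", "AAAA",
             ">x OS = Bos taurus GN = NOTAGENE", "AAAA",
             ">y OS = Bos taurus GN = COL1A1", "AAAA")
  expect_warning(expect_warning(
    db <- parse_database(fasta, gene_set = "COL1A1"),
    "lacking OS="), "unknown gene")
  expect_equal(db$species, "Bos taurus")
})

test_that("unequal aligned lengths within a gene are a hard error naming the gene", {
  fasta <- c(">a OS = A GN = COL1A1", "AAA",
             ">b OS = B GN = COL1A1", "AAAA")
  expect_error(parse_database(fasta, gene_set = "COL1A1"), "COL1A1")
})

test_that("isoforms collapse to a per-column majority consensus", {
  fasta <- c(">a1 OS = A GN = G1", "AC-",
             ">a2 OS = A GN = G1", "AG-")
  db <- parse_database(fasta, gene_set = "G1")
  # tie C/G broken alphabetically; all-gap column stays gap
  expect_equal(unname(db$alignments$G1[["A"]]), "AC-")

  fasta3 <- c(">a1 OS = A GN = G1", "ACA",
              ">a2 OS = A GN = G1", "AG-",
              ">a3 OS = A GN = G1", "-G-")
  db3 <- parse_database(fasta3, gene_set = "G1")
  # col1: 1/3 gaps -> majority A; col2: G majority; col3: 2/3 gaps -> gap
  expect_equal(unname(db3$alignments$G1[["A"]]), "AG-")
})

test_that("ambiguous residues become gaps and sequences are upper-cased", {
  fasta <- c(">a OS = A GN = G1", "axBZu-")
  expect_message(db <- parse_database(fasta, gene_set = "G1"),
                 "non-standard")
  expect_equal(unname(db$alignments$G1[["A"]]), "A-----")
})

test_that("I->L normalization substitutes, preserves the rest, and is idempotent", {
  expect_equal(normalize_il("ISOLATE"), "LSOLATE")
  expect_equal(normalize_il("PEPTDE"), "PEPTDE")
  set.seed(1)
  for (i in 1:20) {
    x <- paste(sample(c(AA, "-"), 30, replace = TRUE), collapse = "")
    expect_identical(normalize_il(normalize_il(x)), normalize_il(x))
  }
  db <- toy_db(list(G1 = c(A = "AIL-", B = "IIII")))
  ndb <- normalize_il(db)
  expect_false(any(grepl("I", unlist(ndb$alignments), fixed = TRUE)))
})

test_that("gene-count filter removes species at the stated boundary and is idempotent", {
  genes <- sprintf("G%02d", 1:20)
  aln <- lapply(genes, function(g) c(full = "AAAA"))
  names(aln) <- genes
  # sp15 present in 15 genes (5 missing, retained); sp14 in 14 (6 missing, removed)
  for (g in genes[1:15]) aln[[g]]["sp15"] <- "CCCC"
  for (g in genes[1:14]) aln[[g]]["sp14"] <- "DDDD"
  db <- toy_db(aln)
  f <- filter_by_gene_count(db, max_missing = 5)
  expect_setequal(f$species, c("full", "sp15"))
  expect_equal(f$removed$species, "sp14")
  f2 <- filter_by_gene_count(f, max_missing = 5)
  expect_setequal(f2$species, f$species)
})

test_that("global index concatenates genes alphabetically and round-trips", {
  db <- toy_db(list(B = c(X = "AA"), A = c(X = "CCC")))
  idx <- build_global_index(db)
  expect_equal(idx$L, 5L)
  expect_equal(global_site(idx, "A", 1:3), 1:3)
  expect_equal(global_site(idx, "B", 1:2), 4:5)

  set.seed(42)
  db2 <- random_toy_db(n_species = 3, genes = c("ZZ", "AA", "MM"),
                       len = c(10, 7, 5))
  idx2 <- build_global_index(db2)
  expect_equal(idx2$L, sum(db2$gene_lengths))
  for (g in db2$genes) {
    for (col in seq_len(db2$gene_lengths[[g]])) {
      back <- site_to_column(idx2, global_site(idx2, g, col))
      expect_identical(back$gene, g)
      expect_identical(back$column, col)
    }
  }
})

test_that("residue maps skip gaps and reconstruct the gapless sequence", {
  db <- toy_db(list(G1 = c(A = "A-C", B = "---")))
  idx <- build_global_index(db)
  rm_ <- build_residue_maps(db, idx)
  expect_equal(rm_$A$G1, c(1L, 3L))
  expect_length(rm_$B$G1, 0L)  # all-gap sequence: empty map

  set.seed(5)
  db2 <- random_toy_db(n_species = 4, gap_prob = 0.25)
  idx2 <- build_global_index(db2)
  rm2 <- build_residue_maps(db2, idx2)
  chars <- global_char_matrix_for_test(db2, idx2)
  for (sp in db2$species) for (g in names(rm2[[sp]])) {
    sites <- rm2[[sp]][[g]]
    expect_true(all(diff(sites) > 0))
    rebuilt <- paste(chars[sites, sp], collapse = "")
    gapless <- gsub("-", "", db2$alignments[[g]][[sp]], fixed = TRUE)
    expect_identical(rebuilt, gapless)
  }
})

test_that("difference matrix matches the brute-force oracle and excludes gaps", {
  db <- toy_db(list(G1 = c(A = "AC-", B = "AG-")))
  idx <- build_global_index(db)
  d <- build_difference_matrix(db, idx)
  expect_equal(nrow(d), 1L)
  expect_equal(d$site, 2L)
  expect_equal(d$aa_a, "C")
  expect_equal(d$aa_b, "G")

  # identical species pair: empty
  db_id <- toy_db(list(G1 = c(A = "ACDE", A2 = "ACDE")))
  expect_equal(nrow(build_difference_matrix(db_id, build_global_index(db_id))), 0L)

  set.seed(9)
  for (rep in 1:5) {
    dbr <- random_toy_db(n_species = 5, gap_prob = 0.15)
    idxr <- build_global_index(dbr)
    got <- as.data.frame(build_difference_matrix(dbr, idxr))
    want <- oracle_diff_matrix(dbr)
    o <- function(x) {
      x <- x[order(x$species_a, x$species_b, x$site), ]
      rownames(x) <- NULL
      x
    }
    expect_equal(o(got), o(want))
    expect_false(any(got$aa_a == "-" | got$aa_b == "-"))
    expect_false(any(got$aa_a == got$aa_b))
  }
})

test_that("gapless FASTA export strips gaps and reparses to the same roster", {
  db <- toy_db(list(G1 = c(A = "AC-E", B = "A-GE"), G2 = c(A = "KK--")))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_database_fasta(db, path, gapless = TRUE)
  txt <- readLines(path)
  expect_false(any(grepl("-", txt[!startsWith(txt, ">")], fixed = TRUE)))
  db2 <- parse_database(path, gene_set = db$genes)
  expect_setequal(db2$species, db$species)
})
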