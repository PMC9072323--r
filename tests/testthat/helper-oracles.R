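# Fixture builders and independent brute-force oracles used across tests.
# The oracles deliberately use naive loops and no package internals beyond
# plain accessors, so they stay independent of the code paths they check.

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# species_db from a plain list: alignments[[gene]][[species]] = aligned string
toy_db <- function(alignments) {
  fasta <- character(0)
  for (g in names(alignments)) {
    for (sp in names(alignments[[g]])) {
      fasta <- c(fasta,
                 sprintf(">%s_%s OS = %s GN = %s", sp, g, sp, g),
                 alignments[[g]][[sp]])
    }
  }
  parse_database(fasta, gene_set = names(alignments))
}

# random toy database: <= 6 species, small genes, random gaps
random_toy_db <- function(n_species = 4, genes = c("GA", "GB"),
                          len = c(30, 20), gap_prob = 0.1) {
  sp <- sprintf("Sp%02d", seq_len(n_species))
  alignments <- list()
  for (gi in seq_along(genes)) {
    alignments[[genes[gi]]] <- sapply(sp, function(s) {
      chars <- sample(AA, len[gi], replace = TRUE)
      chars[runif(len[gi]) < gap_prob] <- "-"
      paste(chars, collapse = "")
    })
  }
  toy_db(alignments)
}

# full-length aligned string of one species, by naive concatenation in
# alphabetical gene order
oracle_global_seq <- function(db, species) {
  paste(vapply(sort(db$genes), function(g) {
    a <- db$alignments[[g]]
    if (species %in% names(a)) a[[species]]
    else strrep("-", if (length(a)) nchar(a[[1]]) else 0)
  }, ""), collapse = "")
}

# character matrix of global aligned sequences (naive version for tests)
global_char_matrix_for_test <- function(db, idx) {
  m <- sapply(sort(db$species), function(sp) {
    strsplit(oracle_global_seq(db, sp), "")[[1]]
  })
  dim(m) <- c(idx$L, length(db$species))
  colnames(m) <- sort(db$species)
  m
}

# brute-force difference matrix: column-by-column comparison of all pairs
oracle_diff_matrix <- function(db) {
  sp <- sort(db$species)
  out <- list()
  for (i in seq_along(sp)) for (j in seq_along(sp)) {
    if (i >= j) next
    a <- strsplit(oracle_global_seq(db, sp[i]), "")[[1]]
    b <- strsplit(oracle_global_seq(db, sp[j]), "")[[1]]
    for (s in seq_along(a)) {
      if (a[s] != "-" && b[s] != "-" && a[s] != b[s]) {
        out[[length(out) + 1]] <- data.frame(
          species_a = sp[i], species_b = sp[j], site = s,
          aa_a = a[s], aa_b = b[s], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(species_a = character(), species_b = character(),
                      site = integer(), aa_a = character(),
                      aa_b = character()))
  }
  do.call(rbind, out)
}

# brute-force peptide annotation: quadratic scan over every start position
# of every species/gene gapless sequence
oracle_annotate <- function(peptides, db) {
  out <- list()
  for (p in unique(peptides)) {
    np <- nchar(p)
    for (sp in db$species) for (g in db$genes) {
      a <- db$alignments[[g]]
      if (!(sp %in% names(a))) next
      aligned <- strsplit(a[[sp]], "")[[1]]
      sites <- which(aligned != "-") +
        sum(db$gene_lengths[sort(db$genes) < g])
      gapless <- paste(aligned[aligned != "-"], collapse = "")
      if (nchar(gapless) < np) next
      for (st in 1:(nchar(gapless) - np + 1)) {
        if (substr(gapless, st, st + np - 1) == p) {
          out[[length(out) + 1]] <- data.frame(
            peptide = p, species = sp, gene = g,
            pos = st:(st + np - 1), site = sites[st:(st + np - 1)],
            aa = strsplit(p, "")[[1]], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(peptide = character(), species = character(),
                      gene = character(), pos = integer(),
                      site = integer(), aa = character()))
  }
  do.call(rbind, out)
}

# brute-force competition: loop over every pair and every difference entry,
# look the J-score up in a plain data.frame
oracle_compete <- function(scores_df, diff_df, species) {
  lookup <- function(s, a) {
    hit <- scores_df$j_score[scores_df$site == s & scores_df$aa == a]
    if (length(hit)) hit[1] else 0
  }
  wins <- setNames(rep(0, length(species)), species)
  for (i in seq_along(species)) for (j in seq_along(species)) {
    if (i >= j) next
    A <- species[i]; B <- species[j]
    d <- diff_df[(diff_df$species_a == A & diff_df$species_b == B) |
                 (diff_df$species_a == B & diff_df$species_b == A), ]
    sa <- sb <- 0
    for (k in seq_len(nrow(d))) {
      if (d$species_a[k] == A) {
        sa <- sa + lookup(d$site[k], d$aa_a[k])
        sb <- sb + lookup(d$site[k], d$aa_b[k])
      } else {
        sa <- sa + lookup(d$site[k], d$aa_b[k])
        sb <- sb + lookup(d$site[k], d$aa_a[k])
      }
    }
    if (sa > sb) wins[A] <- wins[A] + 1
    else if (sb > sa) wins[B] <- wins[B] + 1
    else { wins[A] <- wins[A] + 1; wins[B] <- wins[B] + 1 }
  }
  wins
}

# minimal evidence table in the internal schema
make_evidence <- function(raw_file, stripped, intensity = 1e6, score = 100,
                          charge = 2L, modified = NULL, q = NA_real_) {
  n <- length(stripped)
  data.table::data.table(
    raw_file = rep_len(raw_file, n),
    stripped_seq = chartr("I", "L", stripped),
    modified_seq = modified %||% paste0("_", stripped, "_"),
    charge = rep_len(charge, n),
    intensity = rep_len(intensity, n),
    score = rep_len(score, n),
    precursor_q = rep_len(q, n),
    is_protease = FALSE, is_contaminant = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
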