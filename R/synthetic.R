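#' Simulation configuration
#'
#' Bundles and validates every parameter of the synthetic database and
#' evidence generator. The seed fully determines all output.
#'
#' Defaults describe a desk-scale bone-proteome study: a 30-species
#' database over 6 genes (~3.8k alignment columns), ~8% expected
#' substitutions from root to tip, log-normal MS1 intensities around 1e6,
#' search scores around 100 (floored at 40, the usual DDA identification
#' threshold), 30% semi-tryptic peptides as seen in degraded bone, 5%
#' relative protease intensity in real samples, and blanks whose
#' quantifiable signal is protease autolysis only.
#'
#' @param seed Integer seed.
#' @param n_species Number of database species (>= 2).
#' @param n_novel Extra species simulated but held out of the database.
#' @param gene_lengths Named integer vector of alignment lengths.
#' @param divergence Expected substitutions per site from root to tip.
#' @param missing_gene_rate Probability a database species lacks a gene.
#' @param gap_rate Probability of one gap run in a (species, gene).
#' @param target_site_coverage Distinct residues to cover per sample file.
#' @param p_semitryptic Probability a sampled peptide is semi-tryptic.
#' @param intensity_meanlog,intensity_sdlog Log-normal intensity model.
#' @param score_mean,score_sd,score_min Search-score model (normal,
#'   floored).
#' @param protease_relative_intensity Relative protease intensity of
#'   sample files.
#' @param deamidation_prob Per-residue N/Q deamidation probability.
#' @param p_second_charge Probability a peptide yields a second precursor
#'   at another charge state.
#' @param missed_cleavages Maximum missed cleavages in the digest.
#' @param peptide_length Length range of emitted peptides.
#' @param n_blanks Number of laboratory blanks in the default study plan.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_species = 30L, n_novel = 1L,
                       gene_lengths = c(COL1A1 = 1014L, COL1A2 = 1014L,
                                        COL3A1 = 700L, ALB = 500L,
                                        AHSG = 300L, SPP1 = 250L),
                       divergence = 0.08, missing_gene_rate = 0.05,
                       gap_rate = 0.1, target_site_coverage = 1500L,
                       p_semitryptic = 0.3,
                       intensity_meanlog = log(1e6), intensity_sdlog = 1.2,
                       score_mean = 100, score_sd = 25, score_min = 40,
                       protease_relative_intensity = 0.05,
                       deamidation_prob = 0.2, p_second_charge = 0.2,
                       missed_cleavages = 2L, peptide_length = c(7L, 30L),
                       n_blanks = 3L) {
  cfg <- as.list(environment())
  probs <- c(missing_gene_rate, gap_rate, p_semitryptic,
             protease_relative_intensity, deamidation_prob, p_second_charge)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (n_species < 2L) stop("n_species must be >= 2")
  if (is.null(names(gene_lengths))) stop("gene_lengths must be named")
  if (divergence < 0) stop("divergence must be >= 0")
  structure(cfg, class = "sim_config")
}

# substitute each flagged residue by one of the other 19 amino acids,
# uniformly
mutate_chars <- function(chars, p) {
  idx <- which(stats::runif(length(chars)) < p)
  if (length(idx)) {
    shift <- sample(19L, length(idx), replace = TRUE)
    chars[idx] <- AA20[(match(chars[idx], AA20) + shift - 1L) %% 20L + 1L]
  }
  chars
}

#' Simulate an aligned multi-species database
#'
#' Draws a random coalescent tree over `n_species + n_novel` tips
#' (rescaled so the root-to-tip path equals `divergence` expected
#' substitutions per site), evolves uniformly random root sequences along
#' it with per-site uniform replacement, and assembles a `species_db` from
#' the first `n_species` tips. Database species may lack genes
#' (`missing_gene_rate`) and carry a gap run (`gap_rate`); held-out
#' ("novel") species keep complete sequences and are returned in the
#' `heldout` attribute, for simulating samples whose true species is
#' absent from the database.
#'
#' @param config A [sim_config()].
#' @return A `species_db` with attributes `heldout` (novel species,
#'   `species -> gene -> aligned sequence`) and `tree` (the `phylo` tree).
#' @export
simulate_database <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n_total <- config$n_species + config$n_novel
    tree <- ape::rcoal(n_total)
    depth <- max(ape::node.depth.edgelength(tree))
    if (depth > 0) tree$edge.length <- tree$edge.length / depth * config$divergence
    tree$tip.label <- c(sprintf("Species_%02d", seq_len(config$n_species)),
                        if (config$n_novel > 0)
                          sprintf("Novel_%02d", seq_len(config$n_novel)))
    n_tip <- n_total
    root <- n_tip + 1L
    edges <- tree$edge

    genes <- sort(names(config$gene_lengths))
    tip_seqs <- list()  # species -> gene -> character vector
    for (g in genes) {
      len <- config$gene_lengths[[g]]
      node_seq <- vector("list", max(edges))
      node_seq[[root]] <- sample(AA20, len, replace = TRUE)
      # cladewise edge order visits parents before children
      for (e in seq_len(nrow(edges))) {
        p_sub <- 1 - exp(-tree$edge.length[e])
        node_seq[[edges[e, 2L]]] <-
          mutate_chars(node_seq[[edges[e, 1L]]], p_sub)
      }
      for (t in seq_len(n_tip)) {
        tip_seqs[[tree$tip.label[t]]][[g]] <- node_seq[[t]]
      }
    }

    db_species <- tree$tip.label[seq_len(config$n_species)]
    novel_species <- setdiff(tree$tip.label, db_species)
    alignments <- setNames(vector("list", length(genes)), genes)
    for (g in genes) {
      seqs <- character(0)
      for (sp in db_species) {
        if (stats::runif(1) < config$missing_gene_rate) next
        chars <- tip_seqs[[sp]][[g]]
        if (stats::runif(1) < config$gap_rate) {
          run <- sample(5:25, 1L)
          at <- sample(length(chars) - run, 1L)
          chars[at:(at + run - 1L)] <- GAP
        }
        seqs[sp] <- paste(chars, collapse = "")
      }
      alignments[[g]] <- seqs
    }
    # every species must appear in at least one gene
    for (sp in db_species) {
      if (!any(vapply(alignments, function(a) sp %in% names(a), TRUE))) {
        g <- genes[1]
        alignments[[g]][sp] <- paste(tip_seqs[[sp]][[g]], collapse = "")
      }
    }
    db <- new_species_db(alignments)
    heldout <- lapply(novel_species, function(sp) {
      vapply(genes, function(g) paste(tip_seqs[[sp]][[g]], collapse = ""), "")
    })
    names(heldout) <- novel_species
    attr(db, "heldout") <- heldout
    attr(db, "tree") <- tree
    db
  })
}

#' In-silico protease digestion
#'
#' Cleaves after K or R, suppressed before proline, with up to
#' `missed_cleavages` missed sites. With probability `p_semitryptic` a
#' peptide is truncated at a random internal position on a random side,
#' leaving one non-tryptic terminus (semi-tryptic peptides dominate
#' degraded samples). Peptides outside `length_range` are dropped.
#'
#' @param seqs Named character vector, gene -> gapless sequence.
#' @param p_semitryptic Truncation probability.
#' @param length_range Allowed peptide length (inclusive).
#' @param missed_cleavages Maximum missed cleavages.
#' @return A `data.table` with `gene`, `start`, `end` (1-based residue
#'   coordinates in the source sequence) and `peptide`.
#' @export
digest_in_silico <- function(seqs, p_semitryptic = 0,
                             length_range = c(7L, 30L),
                             missed_cleavages = 2L) {
  pieces <- list(); k <- 0L
  for (g in names(seqs)) {
    s <- seqs[[g]]
    n <- nchar(s)
    if (n == 0L) next
    chars <- strsplit(s, "")[[1]]
    kr <- which(chars %in% c("K", "R"))
    kr <- kr[kr < n & chars[kr + 1L] != "P"]  # no cleavage before proline
    ends <- sort(unique(c(kr, n)))
    starts <- c(1L, head(ends, -1L) + 1L)
    nf <- length(starts)
    for (i in seq_len(nf)) {
      for (j in i:min(nf, i + missed_cleavages)) {
        a <- starts[i]; b <- ends[j]
        if (p_semitryptic > 0 && stats::runif(1) < p_semitryptic &&
            b - a >= 2L) {
          if (stats::runif(1) < 0.5) a <- a + sample(b - a, 1L)
          else b <- b - sample(b - a, 1L)
        }
        len <- b - a + 1L
        if (len < length_range[1] || len > length_range[2]) next
        k <- k + 1L
        pieces[[k]] <- list(gene = g, start = a, end = b,
                            peptide = substr(s, a, b))
      }
    }
  }
  if (!k) {
    return(data.table::data.table(gene = character(), start = integer(),
                                  end = integer(), peptide = character()))
  }
  unique(data.table::rbindlist(pieces))
}

# gapless gene sequences of one species (database or held-out)
species_sequences <- function(db, species) {
  heldout <- attr(db, "heldout")
  if (!is.null(heldout) && species %in% names(heldout)) {
    seqs <- heldout[[species]]
  } else {
    if (!(species %in% db$species)) stop("unknown species: ", species)
    seqs <- vapply(db$genes, function(g) {
      a <- db$alignments[[g]]
      if (species %in% names(a)) a[[species]] else ""
    }, "")
  }
  out <- gsub(GAP, "", seqs, fixed = TRUE)
  out[nzchar(out)]
}

#' Default synthetic contaminant database
#'
#' Path to the synthetic trypsin/Lys-C contaminant FASTA shipped with the
#' package (randomly generated protease-like sequences, not real protease
#' entries).
#'
#' @return File path.
#' @export
synthetic_contaminants <- function() {
  system.file("extdata", "contaminants_synthetic.fasta", package = "protaxa",
              mustWork = TRUE)
}

#' Lay out a synthetic study
#'
#' Builds the per-file plan consumed by [simulate_evidence()]: sample
#' files with a true species drawn from the database roster (or given
#' explicitly), optional files from a held-out novel species, and
#' laboratory blanks.
#'
#' @param simdb Database from [simulate_database()].
#' @param n_samples Number of sample files from database species.
#' @param n_novel_files Number of files from held-out species.
#' @param n_blanks Number of blanks.
#' @param true_species Optional vector of species names recycled over the
#'   sample files; default: drawn uniformly from the roster (requires a
#'   seeded RNG for reproducibility).
#' @return `data.frame` with `raw_file`, `true_species`, `is_blank`.
#' @export
study_plan <- function(simdb, n_samples = 10L, n_novel_files = 0L,
                       n_blanks = 3L, true_species = NULL) {
  targets <- simdb$species[!simdb$is_decoy]
  heldout <- names(attr(simdb, "heldout")) %||% character(0)
  if (n_novel_files > 0L && !length(heldout)) {
    stop("no held-out species available for novel files")
  }
  sp <- if (is.null(true_species)) sample(targets, n_samples, replace = TRUE)
        else rep_len(true_species, n_samples)
  data.frame(
    raw_file = c(sprintf("sample_%03d", seq_len(n_samples)),
                 if (n_novel_files > 0) sprintf("novel_%03d", seq_len(n_novel_files)),
                 if (n_blanks > 0) sprintf("blank_%02d", seq_len(n_blanks))),
    true_species = c(sp,
                     rep_len(heldout, max(n_novel_files, 0L))[seq_len(n_novel_files)],
                     rep(NA_character_, n_blanks)),
    is_blank = c(rep(FALSE, n_samples + n_novel_files), rep(TRUE, n_blanks)),
    stringsAsFactors = FALSE
  )
}

#' Simulate precursor evidence for a study
#'
#' For each sample file, peptides are drawn without replacement from the
#' in-silico digest of the file's true species until the requested number
#' of distinct residues is covered (a warning is raised and the maximum
#' achievable emitted when the digest cannot reach the target). Each drawn
#' peptide becomes a precursor with a sampled charge (2 or 3), log-normal
#' intensity and floored-normal score, occasionally a second precursor at
#' the other charge, and deamidation annotations on N/Q. Protease
#' autolysis peptides are added and scaled so the file's relative protease
#' intensity equals the configured value. Blank files contain protease
#' peptides (the only quantified signal) plus unquantified noise peptides
#' that match nothing in the database.
#'
#' @param simdb Database from [simulate_database()] (pre-normalization;
#'   peptides are I->L normalized in the output).
#' @param config A [sim_config()].
#' @param plan Study plan ([study_plan()]); defaults to 10 samples and
#'   `config$n_blanks` blanks.
#' @param contaminants Contaminant FASTA path; default the synthetic
#'   protease database shipped with the package.
#' @param seed Seed for this evidence draw; defaults to `config$seed`.
#' @return List with `evidence` (internal schema, see [read_evidence()]),
#'   `annotations` (`raw_file`, `is_blank`) and `plan`.
#' @export
simulate_evidence <- function(simdb, config, plan = NULL,
                              contaminants = synthetic_contaminants(),
                              seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    if (is.null(plan)) {
      plan <- study_plan(simdb, n_samples = 10L, n_novel_files = 0L,
                         n_blanks = config$n_blanks)
    }
    cont <- read_fasta_input(contaminants)
    prot_idx <- grepl("trypsin|lys-?c", cont$headers, ignore.case = TRUE)
    prot_seqs <- setNames(toupper(cont$seqs[prot_idx]),
                          sprintf("PROT%02d", seq_len(sum(prot_idx))))
    prot_pool <- digest_in_silico(prot_seqs, p_semitryptic = 0,
                                  length_range = config$peptide_length,
                                  missed_cleavages = config$missed_cleavages)
    db_blob <- paste(unlist(lapply(simdb$alignments, function(a)
      gsub(GAP, "", a, fixed = TRUE))), collapse = "#")
    db_blob <- chartr("I", "L", db_blob)
    prot_blob <- chartr("I", "L", paste(prot_seqs, collapse = "#"))

    digest_cache <- new.env(parent = emptyenv())
    rows <- list(); k <- 0L
    add <- function(x) { k <<- k + 1L; rows[[k]] <<- x }

    for (i in seq_len(nrow(plan))) {
      rf <- plan$raw_file[i]
      if (plan$is_blank[i]) {
        add(protease_rows(rf, prot_pool, target_total = NA, config))
        add(noise_rows(rf, db_blob, prot_blob, config))
        next
      }
      sp <- plan$true_species[i]
      key <- paste0("d_", sp)
      if (!exists(key, envir = digest_cache)) {
        assign(key, digest_in_silico(species_sequences(simdb, sp),
                                     p_semitryptic = config$p_semitryptic,
                                     length_range = config$peptide_length,
                                     missed_cleavages = config$missed_cleavages),
               envir = digest_cache)
      }
      pool <- get(key, envir = digest_cache)
      picked <- sample_to_coverage(pool, config$target_site_coverage)
      if (attr(picked, "coverage") < config$target_site_coverage) {
        warning("file ", rf, ": digest supports only ",
                attr(picked, "coverage"), " covered residues (target ",
                config$target_site_coverage, ")")
      }
      endo <- precursor_rows(rf, picked$peptide, config)
      add(endo)
      r <- config$protease_relative_intensity
      if (r > 0) {
        add(protease_rows(rf, prot_pool,
                          target_total = sum(endo$intensity) * r / (1 - r),
                          config))
      }
    }
    ev <- data.table::rbindlist(rows[seq_len(k)], use.names = TRUE)
    # merge duplicate precursor identities like the readers do
    ev <- ev[, list(stripped_seq = stripped_seq[1],
                    intensity = sum(intensity), score = max(score),
                    precursor_q = NA_real_),
             by = c("raw_file", "modified_seq", "charge")]
    data.table::setcolorder(ev, c("raw_file", "stripped_seq", "modified_seq",
                                  "charge", "intensity", "score",
                                  "precursor_q"))
    ev[, c("is_protease", "is_contaminant") := list(FALSE, FALSE)]
    list(evidence = ev[],
         annotations = plan[, c("raw_file", "is_blank")],
         plan = plan)
  })
}

# draw digest rows in random order until `target` distinct residues of the
# source species are covered
sample_to_coverage <- function(pool, target) {
  pool <- pool[sample(nrow(pool))]
  covered <- new.env(parent = emptyenv())
  for (g in unique(pool$gene)) assign(g, logical(0), envir = covered)
  total <- 0L
  take <- logical(nrow(pool))
  for (i in seq_len(nrow(pool))) {
    if (total >= target) break
    g <- pool$gene[i]
    v <- get(g, envir = covered)
    if (length(v) < pool$end[i]) v <- c(v, logical(pool$end[i] - length(v)))
    rng <- pool$start[i]:pool$end[i]
    gain <- sum(!v[rng])
    v[rng] <- TRUE
    assign(g, v, envir = covered)
    total <- total + gain
    take[i] <- TRUE
  }
  out <- pool[take]
  attr(out, "coverage") <- total
  out
}

# turn peptide strings into precursor evidence rows
precursor_rows <- function(raw_file, peptides, config,
                           intensities = NULL, score_shift = 0) {
  n <- length(peptides)
  if (!n) {
    return(data.table::data.table(raw_file = character(),
                                  stripped_seq = character(),
                                  modified_seq = character(),
                                  charge = integer(), intensity = numeric(),
                                  score = numeric()))
  }
  mod <- vapply(peptides, function(p) {
    chars <- strsplit(p, "")[[1]]
    nq <- which(chars %in% c("N", "Q"))
    hit <- nq[stats::runif(length(nq)) < config$deamidation_prob]
    if (length(hit)) chars[hit] <- paste0(chars[hit], "(de)")
    paste0("_", paste(chars, collapse = ""), "_")
  }, "", USE.NAMES = FALSE)
  charge <- sample(c(2L, 3L), n, replace = TRUE, prob = c(0.7, 0.3))
  intensity <- intensities %||%
    stats::rlnorm(n, config$intensity_meanlog, config$intensity_sdlog)
  score <- pmax(stats::rnorm(n, config$score_mean, config$score_sd),
                config$score_min) + score_shift
  out <- data.table::data.table(
    raw_file = raw_file, stripped_seq = chartr("I", "L", peptides),
    modified_seq = mod, charge = charge, intensity = intensity,
    score = score)
  dup <- which(stats::runif(n) < config$p_second_charge)
  if (length(dup)) {
    second <- out[dup]
    second[, charge := ifelse(charge == 2L, 3L, 2L)]
    second[, intensity := intensity / 2]
    out <- rbind(out, second)
  }
  out
}

# protease autolysis rows; when target_total is given, intensities are
# rescaled so they sum to it (realizing the configured relative protease
# intensity exactly)
protease_rows <- function(raw_file, prot_pool, target_total, config) {
  n <- min(nrow(prot_pool), max(3L, stats::rpois(1L, 10)))
  if (n == 0L) stop("protease digest pool is empty")
  peps <- prot_pool$peptide[sample(nrow(prot_pool), n)]
  ints <- stats::rlnorm(n, config$intensity_meanlog, config$intensity_sdlog)
  if (!is.na(target_total)) ints <- ints / sum(ints) * target_total
  # no second-charge duplicates: keeps the realized protease total exact
  cfg <- config
  cfg$p_second_charge <- 0
  precursor_rows(raw_file, peps, cfg, intensities = ints)
}

# unmatchable noise identifications (blank files); rejected against the
# database and protease sequences, intensity 0 (identified, not quantified)
noise_rows <- function(raw_file, db_blob, prot_blob, config, n = 10L) {
  peps <- character(0)
  while (length(peps) < n) {
    p <- paste(sample(AA20, sample(8:20, 1L), replace = TRUE), collapse = "")
    pl <- chartr("I", "L", p)
    if (!grepl(pl, db_blob, fixed = TRUE) &&
        !grepl(pl, prot_blob, fixed = TRUE)) {
      peps <- c(peps, p)
    }
  }
  rows <- precursor_rows(raw_file, peps, config)
  rows <- rows[!duplicated(paste(modified_seq, charge))]
  rows[, intensity := 0]
  rows[, score := config$score_min]
  rows[]
}
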