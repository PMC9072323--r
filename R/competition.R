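#' Score all species-to-species comparisons for one raw file
#'
#' For every unordered species pair and every site where the pair differs,
#' adds the file's J-score of A's variant to A's sum and of B's variant to
#' B's sum (an unobserved variant contributes 0). The species with the
#' larger sum wins the comparison; equal sums -- including the no-data case
#' where none of the pair's discriminating sites were observed -- are a tie
#' and both species win.
#'
#' @param site_scores J-scored site table ([score_sites()]) for one raw
#'   file (or filtered by `raw_file`).
#' @param diff_matrix Difference matrix from [build_difference_matrix()].
#' @param species Full species roster (targets + decoys).
#' @param raw_file Optional raw file to select from `site_scores`.
#' @return Object of class `competition`: the per-pair sums and outcomes
#'   for pairs with at least one observed discriminating site (all other
#'   pairs are ties), plus the roster.
#' @export
compete <- function(site_scores, diff_matrix, species, raw_file = NULL) {
  if (!length(species)) stop("empty species roster")
  ss <- site_scores
  if (!is.null(raw_file)) {
    rf <- raw_file
    ss <- ss[ss$raw_file == rf]
  }
  d <- diff_matrix[, list(species_a, species_b, site, aa_a, aa_b)]
  sc <- ss[, list(site, aa, j_score)]
  d[sc, on = c(site = "site", aa_a = "aa"), j_a := i.j_score]
  d[sc, on = c(site = "site", aa_b = "aa"), j_b := i.j_score]
  obs <- d[!is.na(j_a) | !is.na(j_b),
           list(sum_a = sum(j_a, na.rm = TRUE),
                sum_b = sum(j_b, na.rm = TRUE),
                n_sites_observed = .N),
           by = c("species_a", "species_b")]
  obs[, outcome := data.table::fifelse(sum_a > sum_b, "A_wins",
                   data.table::fifelse(sum_b > sum_a, "B_wins", "tie"))]
  structure(list(pairs = obs[], species = species, raw_file = raw_file),
            class = "competition")
}

#' @export
print.competition <- function(x, ...) {
  n <- length(x$species)
  cat(sprintf("Species competition: %d species, %d pairs (%d with observed sites)\n",
              n, n * (n - 1) / 2, nrow(x$pairs)))
  invisible(x)
}

#' Win counts and best-matching species
#'
#' Every pair awards one win to its winner, or one win to each species on a
#' tie; pairs with no observed discriminating sites are ties, so "no data"
#' never penalizes either side. Equivalently, a species' win count is
#' (roster size - 1) minus the number of comparisons it lost outright. The
#' best match is the set of species attaining the maximum win count; a set
#' of several species is reported as indistinguishable.
#'
#' @param cm A `competition` object.
#' @return For [competition_wins()], a named integer vector of win counts;
#'   for [best_match()], the character vector of best-matching species.
#' @export
competition_wins <- function(cm) {
  sp <- cm$species
  losses <- setNames(integer(length(sp)), sp)
  p <- cm$pairs
  if (nrow(p)) {
    la <- p$species_a[p$outcome == "B_wins"]
    lb <- p$species_b[p$outcome == "A_wins"]
    tab <- table(c(la, lb))
    losses[names(tab)] <- as.integer(tab)
  }
  (length(sp) - 1L) - losses
}

#' @rdname competition_wins
#' @export
best_match <- function(cm) {
  wins <- competition_wins(cm)
  sort(names(wins)[wins == max(wins)])
}

#' Read and validate a marker-peptide table
#'
#' Markers are hand-picked peptides that discriminate closely related
#' species within a genus (e.g. sheep vs. goat). The table has columns
#' `group`, `species`, `peptide`; peptides must already be I->L normalized.
#'
#' @param path TSV path, or a `data.frame` with the three columns.
#' @param db Optional `species_db`; if given, marker species must exist in
#'   its roster.
#' @return A validated `data.table`.
#' @export
read_marker_table <- function(path, db = NULL) {
  mt <- if (is.data.frame(path)) data.table::as.data.table(path)
        else data.table::fread(path, sep = "\t", showProgress = FALSE)
  need <- c("group", "species", "peptide")
  if (!all(need %in% names(mt))) {
    stop("marker table must have columns ", paste(need, collapse = ", "))
  }
  if (any(grepl("I", mt$peptide, fixed = TRUE))) {
    stop("marker peptides must be I->L normalized (found 'I')")
  }
  if (!is.null(db)) {
    missing <- setdiff(mt$species, db$species)
    if (length(missing)) {
      stop("marker species not in database: ", paste(missing, collapse = ", "))
    }
  }
  mt[, need, with = FALSE]
}

#' Refine a best match by marker-peptide fine-grouping
#'
#' Applied when the best-match set intersects the candidate species of at
#' least one marker group. Each candidate is scored by the summed precursor
#' intensity of its detected marker peptides in the file; the argmax set is
#' returned (ties give multiple indistinguishable species). If no marker
#' peptide is detected the best match is returned unchanged. Fine-grouping
#' never widens taxonomy: its output is restricted to candidates of the
#' intersecting group(s).
#'
#' @param ev Evidence `data.table` (all files).
#' @param marker_table Table from [read_marker_table()].
#' @param best Character vector: the file's best-match set.
#' @param raw_file The raw file to score markers in.
#' @return Character vector: the refined species set.
#' @export
fine_group <- function(ev, marker_table, best, raw_file) {
  if (is.null(marker_table) || !nrow(marker_table)) return(best)
  groups <- unique(marker_table$group[marker_table$species %in% best])
  if (!length(groups)) return(best)
  cand_tab <- marker_table[marker_table$group %in% groups]
  rf <- raw_file
  file_ev <- ev[ev$raw_file == rf]
  candidates <- sort(unique(cand_tab$species))
  score <- vapply(candidates, function(sp) {
    peps <- cand_tab$peptide[cand_tab$species == sp]
    sum(file_ev$intensity[file_ev$stripped_seq %in% peps])
  }, 0)
  detected <- vapply(candidates, function(sp) {
    peps <- cand_tab$peptide[cand_tab$species == sp]
    any(file_ev$stripped_seq %in% peps)
  }, TRUE)
  if (!any(detected)) return(best)
  if (max(score) > 0) sort(candidates[score == max(score)])
  else sort(candidates[detected])
}
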