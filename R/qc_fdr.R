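#' Relative protease intensity of a raw file
#'
#' Summed intensity of protease (trypsin / Lys-C autolysis) precursors
#' divided by the total precursor intensity of the file. Protease peptides
#' behave like a spike-in standard, so a high ratio indicates little
#' endogenous signal -- laboratory blanks sit near 1.
#'
#' @param ev Evidence `data.table` with protease flags set.
#' @param raw_file Raw file id.
#' @return A value in `[0, 1]`; 0 when the file has no intensity at all.
#' @export
relative_protease_intensity <- function(ev, raw_file) {
  rf <- raw_file
  fe <- ev[ev$raw_file == rf]
  tot <- sum(fe$intensity)
  if (tot <= 0) return(0)
  sum(fe$intensity[fe$is_protease]) / tot
}

#' Blank-calibrated protease intensity cutoff
#'
#' The cutoff is the upper quartile (75th percentile, linear-interpolation
#' quantile) of the relative protease intensity among the laboratory
#' blanks. Files at or above the cutoff are flagged `signal_too_low`.
#'
#' @param blank_ratios Relative protease intensities of the blank files.
#' @return The cutoff value.
#' @export
protease_cutoff <- function(blank_ratios) {
  if (!length(blank_ratios)) {
    stop("no laboratory blanks: supply a manual protease-intensity cutoff ",
         "via the `protease_cutoff` argument / config entry")
  }
  unname(stats::quantile(blank_ratios, 0.75, type = 7))
}

#' Absolute sequence coverage of the assigned species
#'
#' Counts the distinct global sites at which an observed amino acid equals
#' the residue of the assigned species. For an indistinguishable set, a
#' site counts when it matches any member (the set is a single taxonomic
#' claim).
#'
#' @param site_scores Site table for one file (any rows with `site`, `aa`).
#' @param assigned Character vector of assigned species.
#' @param reference A `species_reference`.
#' @return Integer site count.
#' @export
site_count <- function(site_scores, assigned, reference) {
  if (!nrow(site_scores) || !length(assigned)) return(0L)
  chars <- reference$global_chars[, intersect(assigned,
                                              colnames(reference$global_chars)),
                                  drop = FALSE]
  if (!ncol(chars)) return(0L)
  sub <- chars[site_scores$site, , drop = FALSE]
  ok <- rowSums(sub == site_scores$aa) > 0
  length(unique(site_scores$site[ok]))
}

#' Coverage-ranked decoy q-values
#'
#' Files are ranked by decreasing site count; at each rank the raw q is the
#' fraction of decoy-only identifications among the top files. Tied site
#' counts share the q of the worst rank in the tie (a single site-count
#' cutoff), and q-values are monotonized by a cumulative minimum from the
#' lowest-coverage rank upward. Files with q above the threshold are
#' flagged. A best match mixing target and decoy species counts as a
#' target identification (a decoy tie should not inflate the FDR).
#'
#' @param results `data.frame` with columns `site_count` and `decoy_only`
#'   (logical).
#' @param q_threshold Flagging threshold (default 0.01).
#' @return The input with added `q_raw`, `q_value` and logical
#'   `above_fdr_threshold`, in the original row order.
#' @export
compute_qvalues <- function(results, q_threshold = 0.01) {
  n <- nrow(results)
  if (!n) {
    results$q_raw <- results$q_value <- numeric(0)
    results$above_fdr_threshold <- logical(0)
    return(results)
  }
  o <- order(-results$site_count)
  sc <- results$site_count[o]
  raw <- cumsum(results$decoy_only[o]) / seq_len(n)
  # ties share the q at the bottom (worst rank) of their tie group
  r <- rle(sc)
  grp_q <- raw[rep(cumsum(r$lengths), r$lengths)]
  qmon <- rev(cummin(rev(grp_q)))
  results$q_raw <- results$q_value <- NA_real_
  results$q_raw[o] <- raw
  results$q_value[o] <- qmon
  results$above_fdr_threshold <- results$q_value > q_threshold
  results
}

#' Consensus sequence of a raw file
#'
#' For every covered global site, the amino acid with the maximal J-score
#' (ties broken alphabetically); uncovered sites are gaps.
#'
#' @param site_scores J-scored site table for one file.
#' @param raw_file Optional raw file to select.
#' @return A `data.table` with `site`, `aa`, sorted by site.
#' @export
consensus_sequence <- function(site_scores, raw_file = NULL) {
  ss <- site_scores
  if (!is.null(raw_file)) {
    rf <- raw_file
    ss <- ss[ss$raw_file == rf]
  }
  if (!nrow(ss)) return(data.table::data.table(site = integer(), aa = character()))
  ss <- ss[order(site, -j_score, aa)]
  ss[!duplicated(site), list(site, aa)]
}

#' Write per-sample consensus sequences as FASTA
#'
#' One record per raw file, full alignment length, gaps at uncovered sites.
#'
#' @param site_scores J-scored site table (all files).
#' @param reference A `species_reference`.
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_consensus_fasta <- function(site_scores, reference, path) {
  L <- reference$index$L
  files <- sort(unique(site_scores$raw_file))
  seqs <- vapply(files, function(f) {
    cons <- consensus_sequence(site_scores, f)
    chars <- rep(GAP, L)
    chars[cons$site] <- cons$aa
    paste(chars, collapse = "")
  }, "")
  names(seqs) <- paste0(files, " consensus")
  write_fasta(seqs, path)
}

#' Deamidation fractions of a raw file
#'
#' Fraction of asparagine (N) and glutamine (Q) residue occurrences carrying
#' a deamidation annotation in the modified sequence, across all precursors
#' of the file. Deamidation accumulates in ancient proteins, so higher
#' fractions indicate more degraded samples. Recognizes MaxQuant-style
#' `N(de)` / `N(Deamidation (NQ))` and Spectronaut-style `N[Deamidated
#' (NQ)]` notation.
#'
#' @param ev Evidence `data.table`.
#' @param raw_file Raw file id.
#' @return Named numeric vector `c(N = ..., Q = ...)`; `NA` where the file
#'   contains no residue of that type.
#' @export
deamidation_fractions <- function(ev, raw_file) {
  rf <- raw_file
  fe <- ev[ev$raw_file == rf]
  count_matches <- function(pattern, x) {
    if (!length(x)) return(0L)
    sum(vapply(gregexpr(pattern, x, perl = TRUE), function(m) {
      if (m[1] == -1L) 0L else length(m)
    }, 0L))
  }
  out <- c(N = NA_real_, Q = NA_real_)
  for (res in c("N", "Q")) {
    total <- count_matches(res, fe$stripped_seq)
    if (total == 0L) next
    deam <- count_matches(
      sprintf("%s(\\(de\\)|\\(Deamidation[^)]*\\)|\\[Deamidated[^]]*\\])", res),
      fe$modified_seq)
    out[res] <- deam / total
  }
  out
}
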