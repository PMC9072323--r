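#' Aggregate annotated precursors into site-level metrics
#'
#' Converts peptide identifications into amino-acid identifications: for
#' every (raw file, global site, amino acid) observed, counts distinct
#' precursors (modified sequence + charge) and distinct peptides (stripped
#' sequence), sums precursor intensities and takes the maximum search
#' score. A precursor matching several species contributes once per covered
#' site, not once per species. Protease-flagged precursors never contribute.
#'
#' @param annotated Result of [annotate_evidence()] (list with `evidence`
#'   and `hits`).
#' @return A `data.table` with one row per (raw_file, site, aa):
#'   `n_precursors`, `n_peptides`, `sum_intensity`, `max_score`.
#' @export
aggregate_sites <- function(annotated) {
  ev <- annotated$evidence
  hits <- annotated$hits
  empty <- data.table::data.table(
    raw_file = character(), site = integer(), aa = character(),
    n_precursors = integer(), n_peptides = integer(),
    sum_intensity = numeric(), max_score = numeric())
  if (!nrow(hits)) return(empty)
  # Union of covered (site, aa) per peptide across all matched species.
  pep_sites <- unique(hits[, list(peptide, site, aa)])
  use <- ev[!is_protease & matched,
            list(raw_file, stripped_seq, modified_seq, charge,
                 intensity, score)]
  if (!nrow(use)) return(empty)
  m <- pep_sites[use, on = c(peptide = "stripped_seq"),
                 allow.cartesian = TRUE, nomatch = NULL]
  m[, list(
    n_precursors = data.table::uniqueN(paste(modified_seq, charge)),
    n_peptides = data.table::uniqueN(peptide),
    sum_intensity = sum(intensity),
    max_score = max(score)
  ), by = c("raw_file", "site", "aa")]
}

#' Compute the normalized joint score (J-score)
#'
#' Summed intensities larger than 1 are log10-transformed (0 otherwise);
#' precursor count, peptide count, log-intensity and maximum score are each
#' scaled by dividing by their maximum over the amino acids observed at the
#' same (raw file, global site); the four scaled metrics are multiplied,
#' and the product is rescaled by the maximum product at the site, giving a
#' J-score in `[0, 1]` with at least one amino acid at 1 per covered site.
#' A metric whose per-site maximum is 0 (e.g. all intensities at or below
#' 1, or all scores at 0 after clamping negatives) is neutral: it
#' contributes a factor of 1 for every amino acid at that site rather than
#' 0/0. The J-score weights amino acids by the strength of their underlying
#' evidence; it is not a calibrated amino-acid probability.
#'
#' @param site_table Output of [aggregate_sites()].
#' @return The table with added columns `log_intensity`, `scaled_*`,
#'   `j_score`.
#' @export
score_sites <- function(site_table) {
  st <- data.table::copy(site_table)
  if (!nrow(st)) {
    st[, c("log_intensity", "scaled_n_precursors", "scaled_n_peptides",
           "scaled_log_intensity", "scaled_max_score", "j_score") :=
         list(numeric(), numeric(), numeric(), numeric(), numeric(),
              numeric())]
    return(st[])
  }
  st[, log_intensity := ifelse(sum_intensity > 1, log10(sum_intensity), 0)]
  scale_max <- function(x) {
    m <- max(x)
    if (m <= 0) rep(1, length(x)) else x / m
  }
  st[, scaled_n_precursors := scale_max(n_precursors),
     by = c("raw_file", "site")]
  st[, scaled_n_peptides := scale_max(n_peptides), by = c("raw_file", "site")]
  st[, scaled_log_intensity := scale_max(log_intensity),
     by = c("raw_file", "site")]
  st[, scaled_max_score := scale_max(pmax(max_score, 0)),
     by = c("raw_file", "site")]
  st[, j_score := {
    raw <- scaled_n_precursors * scaled_n_peptides * scaled_log_intensity *
      scaled_max_score
    m <- max(raw)
    if (m > 0) raw / m else rep(0, length(raw))
  }, by = c("raw_file", "site")]
  st[]
}
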