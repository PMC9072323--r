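#' Build a species inference reference
#'
#' One-stop constructor for everything the inference needs from the aligned
#' database: parses (if given FASTA), applies I->L normalization, removes
#' species with too many missing genes, appends chimeric decoy species,
#' builds the global site index, residue maps, the substring-search index,
#' and the site-specific species difference matrix over the combined
#' target+decoy roster.
#'
#' @param db A `species_db`, or a FASTA path / text to pass through
#'   [parse_database()].
#' @param gene_set Gene set for parsing (ignored when `db` is already a
#'   `species_db`).
#' @param max_missing Gene-count filter threshold (default 5); use `Inf` to
#'   disable.
#' @param add_decoys Generate decoys when the database has none yet.
#' @param n_decoys,slice_len,seed Passed to [generate_decoys()].
#' @return Object of class `species_reference` with elements `db`, `index`,
#'   `residue_maps`, `match_index`, `diff`, `global_chars`.
#' @export
build_reference <- function(db, gene_set = bone_gene_set(), max_missing = 5L,
                            add_decoys = TRUE, n_decoys = NULL,
                            slice_len = 500L, seed = NULL) {
  if (!inherits(db, "species_db")) {
    db <- parse_database(db, gene_set = gene_set)
  }
  db <- normalize_il(db)
  if (is.finite(max_missing)) db <- filter_by_gene_count(db, max_missing)
  index <- build_global_index(db)
  if (add_decoys && !any(db$is_decoy)) {
    db <- generate_decoys(db, index, slice_len = slice_len,
                          n_decoys = n_decoys, seed = seed)
  }
  residue_maps <- build_residue_maps(db, index)
  structure(list(
    db = db,
    index = index,
    residue_maps = residue_maps,
    match_index = build_match_index(db, index, residue_maps),
    diff = build_difference_matrix(db, index),
    global_chars = global_char_matrix(db, index)
  ), class = "species_reference")
}

#' @export
print.species_reference <- function(x, ...) {
  cat("Species inference reference\n")
  cat(sprintf("  %d target + %d decoy species, %d genes, L = %d global sites\n",
              sum(!x$db$is_decoy), sum(x$db$is_decoy),
              sum(x$db$gene_lengths > 0), x$index$L))
  cat(sprintf("  difference matrix: %d discriminating-site entries over %d pairs\n",
              nrow(x$diff),
              length(x$db$species) * (length(x$db$species) - 1) / 2))
  if (!is.null(x$db$removed) && nrow(x$db$removed)) {
    cat(sprintf("  %d species removed by the gene-count filter\n",
                nrow(x$db$removed)))
  }
  invisible(x)
}
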