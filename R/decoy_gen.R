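#' Extend a target database with chimeric decoy species
#'
#' Decoy species estimate the species-level false-discovery rate: each decoy
#' is assembled by slicing the global alignment into `slice_len`-column
#' pieces (the final slice may be shorter) and copying every slice verbatim
#' -- gaps included -- from a target species drawn uniformly at random, with
#' replacement across slices. A decoy whose full aligned sequence reproduces
#' a target is rejected and regenerated. Best-matches to decoys downstream
#' feed the coverage-ranked q-value.
#'
#' @param db Filtered target `species_db`.
#' @param index The matching `global_site_index`.
#' @param slice_len Slice width in alignment columns (default 500).
#' @param n_decoys Number of decoys; defaults to the number of target
#'   species, giving a 1:1 target/decoy roster.
#' @param seed Optional integer seed for reproducible decoys (the session
#'   RNG stream is restored afterwards).
#' @param prefix Reserved name prefix for decoy species.
#' @return The `species_db` with decoys appended; the `decoy_provenance`
#'   element records, per decoy and slice, the source species and the
#'   global-site interval copied.
#' @export
generate_decoys <- function(db, index, slice_len = 500L, n_decoys = NULL,
                            seed = NULL, prefix = db$decoy_prefix) {
  if (slice_len < 1L) stop("slice_len must be >= 1")
  targets <- db$species[!db$is_decoy]
  if (!length(targets)) stop("empty target roster: nothing to build decoys from")
  if (any(startsWith(targets, prefix))) {
    stop("target species name collides with the decoy prefix '", prefix, "'")
  }
  n_decoys <- as.integer(n_decoys %||% length(targets))
  L <- index$L
  starts <- seq(1L, L, by = as.integer(slice_len))
  ends <- pmin(starts + as.integer(slice_len) - 1L, L)
  if (length(starts) < 2L && length(targets) > 1L) {
    stop("slice_len (", slice_len, ") spans the whole alignment (L = ", L,
         "): every decoy would be a verbatim copy of a target; ",
         "choose a smaller slice_len")
  }
  tmat <- global_char_matrix(db, index, targets)
  target_strings <- apply(tmat, 2L, paste, collapse = "")

  with_seed(seed, {
    prov <- vector("list", n_decoys)
    chim_list <- vector("list", n_decoys)
    for (d in seq_len(n_decoys)) {
      name <- sprintf("%s%03d", prefix, d)
      for (try in seq_len(100L)) {
        src <- sample(targets, length(starts), replace = TRUE)
        chim <- character(L)
        for (s in seq_along(starts)) {
          rng <- starts[s]:ends[s]
          chim[rng] <- tmat[rng, src[s]]
        }
        if (!(paste(chim, collapse = "") %in% target_strings)) break
        if (try == 100L) stop("could not generate a decoy distinct from all targets")
      }
      chim_list[[d]] <- chim
      prov[[d]] <- data.table::data.table(
        decoy = name, slice = seq_along(starts),
        start = starts, end = ends, source = src)
    }
    for (d in seq_len(n_decoys)) {
      name <- sprintf("%s%03d", prefix, d)
      chim <- chim_list[[d]]
      for (g in db$genes) {
        gl <- index$gene_lengths[g]
        if (gl == 0L) next
        seg <- paste(chim[(index$offsets[g] + 1L):(index$offsets[g] + gl)],
                     collapse = "")
        db$alignments[[g]][name] <- seg
      }
    }
    taxa <- db$taxa
    removed <- db$removed
    db <- new_species_db(db$alignments, prefix)
    db$taxa <- taxa
    db$removed <- removed
    db$decoy_provenance <- data.table::rbindlist(prov)
    db
  })
}
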