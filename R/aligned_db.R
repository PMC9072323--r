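#' Default bone proteome gene set
#'
#' The 20 most highly expressed protein-coding genes in mammalian bone, used
#' as the default gene set for the aligned species database. Databases built
#' for other tissues can supply their own gene set to [parse_database()].
#'
#' @return Character vector of 20 gene symbols, alphabetically sorted.
#' @export
bone_gene_set <- function() {
  sort(c("AHSG", "ALB", "APOA1", "BGN", "CHAD", "COL1A1", "COL1A2", "COL3A1",
         "COL5A1", "COL5A2", "COL11A1", "COL11A2", "COL22A1", "COL24A1",
         "LUM", "OMD", "PCOLCE", "SERPINC1", "SPP1", "VIM"))
}

# Parse one FASTA header into species / taxon / gene / source.
# Accepts standard UniProt ("OS=Bos taurus OX=9913 GN=COL1A1") and the
# pseudo-UniProt dialect with spaces around '=' used for re-annotated NCBI
# entries (">NCBI | XP_1 | XP_1_COL1A1 ... OS = Bos taurus OX = 9913 GN = COL1A1").
parse_fasta_header <- function(header) {
  grab <- function(tag, stop_tags = "OS|OX|GN") {
    m <- regmatches(header,
      regexec(sprintf("%s ?= ?(.*?)(?= (?:%s) ?=|$)", tag, stop_tags),
              header, perl = TRUE))[[1]]
    if (length(m) < 2L) NA_character_ else trimws(m[2])
  }
  species <- grab("OS")
  taxon <- suppressWarnings(as.integer(grab("OX")))
  gene <- grab("GN")
  source <- if (grepl("^NCBI *\\|", header)) "ncbi"
    else if (grepl("^(sp|tr)\\|", header)) "uniprot"
    else if (grepl("UniRef", header, ignore.case = TRUE)) "uniref-annotated"
    else "manual"
  list(species = species, taxon = taxon, gene = gene, source = source)
}

# Per-column majority consensus over isoforms of one (species, gene).
# A column becomes a gap when more than half the isoforms have a gap there;
# otherwise the most frequent non-gap amino acid wins, ties alphabetically.
collapse_isoforms <- function(seqs) {
  if (length(seqs) == 1L) return(seqs[[1]])
  m <- do.call(rbind, strsplit(seqs, ""))
  paste(apply(m, 2L, function(col) {
    if (mean(col == GAP) > 0.5) return(GAP)
    col <- col[col != GAP]
    if (!length(col)) return(GAP)
    tab <- table(col)
    sort(names(tab)[tab == max(tab)])[1]
  }), collapse = "")
}

#' Parse a gene-wise aligned multi-species protein database
#'
#' Reads a multi-FASTA of aligned protein sequences whose headers carry
#' `OS=` (species), `OX=` (taxon id) and `GN=` (gene) tags, either in
#' standard UniProt form or in the pseudo-UniProt dialect used for
#' re-annotated NCBI entries. Records are grouped by (species, gene);
#' multiple isoforms are collapsed to a per-column majority consensus.
#' Sequences are upper-cased, and characters outside the 20 amino acids and
#' the gap `'-'` (X, B, Z, U, ...) are converted to gaps because they cannot
#' participate in site comparisons.
#'
#' @param fasta A file path or a character vector of FASTA text.
#' @param gene_set Character vector of accepted gene symbols; records with a
#'   `GN=` outside this set are dropped with a warning. Default
#'   [bone_gene_set()].
#' @param decoy_prefix Species names starting with this prefix are flagged as
#'   decoy species (used when re-loading a previously exported target+decoy
#'   database).
#' @return An object of class `species_db`: gene-keyed alignments, the
#'   species roster with per-species gene counts, and decoy flags.
#' @export
parse_database <- function(fasta, gene_set = bone_gene_set(),
                           decoy_prefix = "DECOY_") {
  fa <- read_fasta_input(fasta)
  genes <- sort(unique(gene_set))
  if (!length(fa$headers)) {
    return(new_species_db(setNames(vector("list", length(genes)), genes),
                          decoy_prefix))
  }
  info <- lapply(fa$headers, parse_fasta_header)
  species <- vapply(info, function(x) x$species %||% NA_character_, "")
  gene <- vapply(info, function(x) x$gene %||% NA_character_, "")
  taxon <- vapply(info, function(x) x$taxon %||% NA_integer_, 1L)

  bad <- is.na(species) | species == "" | is.na(gene)
  if (any(bad)) {
    warning(sum(bad), " record(s) rejected: header lacking OS= or GN= tags")
  }
  unknown <- !bad & !(gene %in% genes)
  if (any(unknown)) {
    warning(sum(unknown), " record(s) rejected: unknown gene symbol(s) ",
            paste(unique(gene[unknown]), collapse = ", "))
  }
  keep <- !bad & !unknown
  species <- species[keep]; gene <- gene[keep]; taxon <- taxon[keep]
  seqs <- toupper(fa$seqs[keep])

  # Non-standard residues cannot carry site information: convert to gaps.
  n_odd <- sum(nchar(gsub(sprintf("[%s-]", paste(AA20, collapse = "")), "", seqs)))
  if (n_odd > 0) {
    message(n_odd, " non-standard residue(s) converted to gaps")
    seqs <- gsub(sprintf("[^%s-]", paste(AA20, collapse = "")), GAP, seqs)
  }

  alignments <- setNames(vector("list", length(genes)), genes)
  taxa <- list()
  for (g in genes) {
    idx <- which(gene == g)
    if (!length(idx)) { alignments[[g]] <- character(0); next }
    lens <- nchar(seqs[idx])
    if (length(unique(lens)) > 1L) {
      stop("unequal aligned sequence lengths within gene ", g,
           " (found lengths ", paste(unique(lens), collapse = ", "), ")")
    }
    by_sp <- split(seqs[idx], species[idx])
    alignments[[g]] <- vapply(by_sp, collapse_isoforms, "")
    for (sp in unique(species[idx])) {
      tx <- taxon[idx][species[idx] == sp]
      tx <- tx[!is.na(tx)]
      if (length(tx)) taxa[[sp]] <- tx[1]
    }
  }
  db <- new_species_db(alignments, decoy_prefix)
  db$taxa <- unlist(taxa)
  db
}

new_species_db <- function(alignments, decoy_prefix = "DECOY_") {
  alignments <- alignments[sort(names(alignments))]
  species <- sort(unique(unlist(lapply(alignments, names), use.names = FALSE)))
  species <- as.character(species %||% character(0))
  gene_lengths <- vapply(alignments, function(a) {
    if (length(a)) nchar(a[[1]]) else 0L
  }, 0L)
  gene_counts <- vapply(species, function(sp) {
    sum(vapply(alignments, function(a) sp %in% names(a), TRUE))
  }, 0L)
  structure(list(
    genes = names(alignments),
    alignments = alignments,
    gene_lengths = gene_lengths,
    species = species,
    gene_counts = gene_counts,
    is_decoy = setNames(startsWith(species, decoy_prefix), species),
    decoy_prefix = decoy_prefix
  ), class = "species_db")
}

#' @export
print.species_db <- function(x, ...) {
  cat("Aligned species database\n")
  cat(sprintf("  %d species (%d decoy), %d/%d genes populated, %d total columns\n",
              length(x$species), sum(x$is_decoy),
              sum(x$gene_lengths > 0), length(x$genes),
              sum(x$gene_lengths)))
  invisible(x)
}

#' Replace isoleucine by leucine
#'
#' Isoleucine and leucine are isobaric and indistinguishable by standard
#' tandem MS, so both the database and all peptide sequences are projected
#' onto 'L' before any matching.
#'
#' @param x A character vector of sequences or a `species_db`.
#' @return Same type as `x` with every 'I' replaced by 'L'.
#' @export
normalize_il <- function(x) UseMethod("normalize_il")

#' @export
normalize_il.character <- function(x) chartr("I", "L", x)

#' @export
normalize_il.species_db <- function(x) {
  x$alignments <- lapply(x$alignments, function(a) {
    out <- chartr("I", "L", a)
    names(out) <- names(a)
    out
  })
  x
}

#' Remove species with too many missing genes
#'
#' Species lacking more than `max_missing` of the configured genes cannot be
#' assigned reliably and are dropped from the target roster. Decoy species
#' are exempt (they are generated after filtering and may inherit gaps).
#'
#' @param db A `species_db`.
#' @param max_missing Maximum tolerated number of missing genes (default 5
#'   of 20).
#' @return The filtered `species_db`; the removed species and their gene
#'   counts are recorded in the `removed` element.
#' @export
filter_by_gene_count <- function(db, max_missing = 5L) {
  # count against the genes actually populated in this database
  need <- sum(db$gene_lengths > 0) - max_missing
  drop <- db$species[!db$is_decoy & db$gene_counts < need]
  report <- data.frame(species = drop,
                       genes_present = unname(db$gene_counts[drop]),
                       stringsAsFactors = FALSE)
  if (length(drop)) {
    taxa <- db$taxa
    prev <- db$removed
    db$alignments <- lapply(db$alignments, function(a) a[!(names(a) %in% drop)])
    db <- new_species_db(db$alignments, db$decoy_prefix)
    db$taxa <- taxa
    db$removed <- prev
  }
  db$removed <- rbind(db$removed, report)
  db
}

#' Build the global site index
#'
#' Assigns every alignment column a 1-based "global site" by concatenating
#' the gene alignments in alphabetical gene order: sites of the first gene
#' run from 1 to its alignment length, the next gene continues from there,
#' and so on up to the total length L.
#'
#' @param db A `species_db`.
#' @return An object of class `global_site_index` with the total length `L`,
#'   per-gene offsets and the forward/inverse maps [global_site()] and
#'   [site_to_column()].
#' @export
build_global_index <- function(db) {
  lens <- db$gene_lengths
  offsets <- c(0L, cumsum(as.integer(lens)))[seq_along(lens)]
  names(offsets) <- names(lens)
  structure(list(L = sum(lens), gene_lengths = lens, offsets = offsets),
            class = "global_site_index")
}

#' @rdname build_global_index
#' @param index A `global_site_index`.
#' @param gene Gene symbol.
#' @param column 1-based alignment column within `gene`.
#' @export
global_site <- function(index, gene, column) {
  stopifnot(all(column >= 1L), all(column <= index$gene_lengths[gene]))
  unname(index$offsets[gene] + as.integer(column))
}

#' @rdname build_global_index
#' @param site Global site in `1..L`.
#' @export
site_to_column <- function(index, site) {
  stopifnot(all(site >= 1L), all(site <= index$L))
  bounds <- cumsum(as.integer(index$gene_lengths))
  i <- findInterval(site - 1L, c(0L, bounds), rightmost.closed = FALSE)
  data.frame(gene = names(index$gene_lengths)[i],
             column = as.integer(site) - unname(index$offsets[i]),
             stringsAsFactors = FALSE)
}

# Full-length (L characters) aligned sequence of one species: per-gene
# aligned sequences in gene order, all-gap stretches for absent genes.
global_sequence <- function(db, index, species) {
  parts <- vapply(db$genes, function(g) {
    a <- db$alignments[[g]]
    if (species %in% names(a)) a[[species]]
    else strrep(GAP, index$gene_lengths[g])
  }, "")
  paste(parts, collapse = "")
}

# Character matrix L x n_species of the global aligned sequences.
global_char_matrix <- function(db, index, species = db$species) {
  m <- vapply(species, function(sp) {
    strsplit(global_sequence(db, index, sp), "")[[1]]
  }, character(index$L))
  dim(m) <- c(index$L, length(species))
  colnames(m) <- species
  m
}

#' Map gapless residue positions to global sites
#'
#' For every (species, gene) the k-th non-gap character of the aligned
#' sequence is mapped to the global site of its alignment column, so that
#' peptide matches against gapless sequences can be lifted into global
#' coordinates.
#'
#' @param db A `species_db`.
#' @param index The matching `global_site_index`.
#' @return Nested list `species -> gene -> integer vector of global sites`
#'   (strictly increasing, one entry per gapless residue).
#' @export
build_residue_maps <- function(db, index) {
  out <- lapply(db$species, function(sp) {
    maps <- list()
    for (g in db$genes) {
      a <- db$alignments[[g]]
      if (!(sp %in% names(a))) next
      chars <- strsplit(a[[sp]], "")[[1]]
      maps[[g]] <- unname(index$offsets[g]) + which(chars != GAP)
    }
    maps
  })
  names(out) <- db$species
  out
}

#' Build the site-specific species difference matrix
#'
#' For every unordered pair of species in the roster (targets and decoys
#' alike), lists the global sites where the two species carry different
#' amino acids. Sites where either species has a gap are ignored.
#'
#' @param db A `species_db` (one representative sequence per species/gene).
#' @param index The matching `global_site_index`.
#' @return A `data.table` with columns `species_a`, `species_b` (with
#'   `species_a < species_b`), `site`, `aa_a`, `aa_b`.
#' @export
build_difference_matrix <- function(db, index) {
  sp <- db$species
  m <- global_char_matrix(db, index, sp)
  pieces <- vector("list", length(sp) * (length(sp) - 1L) / 2L)
  k <- 0L
  if (length(sp) >= 2L) {
    for (i in seq_len(length(sp) - 1L)) {
      ci <- m[, i]
      for (j in (i + 1L):length(sp)) {
        cj <- m[, j]
        d <- which(ci != cj & ci != GAP & cj != GAP)
        k <- k + 1L
        if (length(d)) {
          pieces[[k]] <- data.table::data.table(
            species_a = sp[i], species_b = sp[j],
            site = d, aa_a = ci[d], aa_b = cj[d])
        }
      }
    }
  }
  out <- data.table::rbindlist(pieces[seq_len(k)], use.names = TRUE)
  if (!nrow(out)) {
    out <- data.table::data.table(species_a = character(), species_b = character(),
                                  site = integer(), aa_a = character(),
                                  aa_b = character())
  }
  data.table::setkey(out, site, aa_a)
  out[]
}

#' Export the database as FASTA
#'
#' Writes one record per (species, gene) with an `OS = ... GN = ...` header.
#' The aligned variant keeps gap characters; the gapless variant strips them
#' for use as a search-engine database.
#'
#' @param db A `species_db`.
#' @param path Output file.
#' @param gapless Strip gap characters when `TRUE`.
#' @return The path, invisibly.
#' @export
write_database_fasta <- function(db, path, gapless = FALSE) {
  seqs <- character(0)
  for (g in db$genes) {
    a <- db$alignments[[g]]
    if (!length(a)) next
    hdr <- sprintf("%s_%s %s OS = %s GN = %s", names(a), g,
                   ifelse(db$is_decoy[names(a)], "decoy", "target"),
                   names(a), g)
    s <- if (gapless) gsub(GAP, "", a, fixed = TRUE) else a
    names(s) <- hdr
    seqs <- c(seqs, s)
  }
  write_fasta(seqs, path)
}
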