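#' Evidence dialect column maps
#'
#' Column-name maps for the two supported precursor-table dialects: the
#' `evidence.txt` layout written by MaxQuant (DDA) and a Spectronaut report
#' layout (DIA). The `qvalue` entry may be `NA`: MaxQuant evidence tables
#' are already FDR-filtered by the search engine and carry no q-value
#' column.
#'
#' @return Named list of column maps.
#' @export
evidence_dialects <- function() {
  list(
    maxquant_evidence = c(
      raw_file = "Raw file", stripped_seq = "Sequence",
      modified_seq = "Modified sequence", charge = "Charge",
      intensity = "Intensity", score = "Score",
      precursor_q = NA, proteins = "Proteins"),
    spectronaut_report = c(
      raw_file = "R.FileName", stripped_seq = "PEP.StrippedSequence",
      modified_seq = "EG.ModifiedSequence", charge = "FG.Charge",
      intensity = "FG.MS1Quantity", score = "EG.Cscore",
      precursor_q = "EG.Qvalue", proteins = "PG.ProteinAccessions")
  )
}

#' Read a precursor identification table
#'
#' Reads a TSV of identified peptide precursors in one of the two supported
#' dialects (or with a custom column map), normalizes it to the internal
#' schema, applies I->L replacement to the stripped sequence, and merges
#' duplicate precursor identities -- (raw file, modified sequence, charge)
#' -- by summing intensity and keeping the maximum score. Missing
#' intensities become 0: such rows still contribute identification counts
#' and scores.
#'
#' @param path TSV file path.
#' @param dialect `"maxquant_evidence"` or `"spectronaut_report"`.
#' @param column_map Optional named character vector overriding the
#'   dialect's map (names: `raw_file`, `stripped_seq`, `modified_seq`,
#'   `charge`, `intensity`, `score`, optionally `precursor_q`).
#' @return A `data.table` with columns `raw_file`, `stripped_seq`,
#'   `modified_seq`, `charge`, `intensity`, `score`, `precursor_q`,
#'   `is_protease`, `is_contaminant`.
#' @export
read_evidence <- function(path, dialect = c("maxquant_evidence",
                                            "spectronaut_report"),
                          column_map = NULL) {
  if (is.null(column_map)) {
    dialect <- match.arg(dialect)
    column_map <- evidence_dialects()[[dialect]]
  }
  tab <- data.table::fread(path, sep = "\t", colClasses = "character",
                           showProgress = FALSE)
  required <- c("raw_file", "stripped_seq", "modified_seq", "charge",
                "intensity", "score")
  for (lc in required) {
    if (!(column_map[[lc]] %in% names(tab))) {
      stop("evidence table is missing required column '", column_map[[lc]],
           "' (", lc, ")")
    }
  }
  ev <- data.table::data.table(
    raw_file = tab[[column_map[["raw_file"]]]],
    stripped_seq = toupper(chartr("I", "L", tab[[column_map[["stripped_seq"]]]])),
    modified_seq = tab[[column_map[["modified_seq"]]]],
    charge = suppressWarnings(as.integer(tab[[column_map[["charge"]]]])),
    intensity = suppressWarnings(as.numeric(tab[[column_map[["intensity"]]]])),
    score = suppressWarnings(as.numeric(tab[[column_map[["score"]]]]))
  )
  qcol <- column_map[["precursor_q"]]
  ev$precursor_q <- if (!is.na(qcol) && qcol %in% names(tab)) {
    suppressWarnings(as.numeric(tab[[qcol]]))
  } else NA_real_
  ev$intensity[is.na(ev$intensity)] <- 0
  bad <- is.na(ev$charge) | is.na(ev$score) | is.na(ev$raw_file) |
    ev$stripped_seq == ""
  if (any(bad)) {
    warning(sum(bad), " row(s) skipped: unparsable charge/score or empty sequence")
    ev <- ev[!bad]
  }
  ev <- ev[, list(
    stripped_seq = stripped_seq[1],
    intensity = sum(intensity),
    score = max(score),
    precursor_q = if (all(is.na(precursor_q))) NA_real_ else
      min(precursor_q, na.rm = TRUE)
  ), by = c("raw_file", "modified_seq", "charge")]
  data.table::setcolorder(ev, c("raw_file", "stripped_seq", "modified_seq",
                                "charge", "intensity", "score", "precursor_q"))
  ev[, c("is_protease", "is_contaminant") := list(FALSE, FALSE)]
  ev[]
}

#' Filter precursors by identification q-value
#'
#' Removes precursors with `precursor_q > alpha`. Records without a q-value
#' pass unchanged: MaxQuant evidence tables are pre-filtered at 1% FDR by
#' the search engine and carry no q-value column.
#'
#' @param ev Evidence `data.table` from [read_evidence()].
#' @param alpha Precursor FDR threshold (default 0.01).
#' @return Filtered evidence table.
#' @export
filter_precursor_fdr <- function(ev, alpha = 0.01) {
  ev[is.na(precursor_q) | precursor_q <= alpha]
}

#' Flag protease and contaminant precursors
#'
#' Marks precursors whose stripped sequence occurs as a substring of any
#' contaminant entry (after I->L). Entries whose headers match
#' `protease_pattern` (trypsin / Lys-C by default) additionally set
#' `is_protease`: protease autolysis products are treated as a spike-in
#' standard -- they are excluded from species scoring even when their
#' sequence also occurs in a target protein, but they are retained in the
#' table and count towards total intensity.
#'
#' @param ev Evidence `data.table`.
#' @param contaminant_fasta Path or FASTA text of contaminant sequences.
#' @param protease_pattern Case-insensitive regex identifying protease
#'   entries by header.
#' @return The evidence table with `is_protease` / `is_contaminant` set.
#' @export
flag_contaminants <- function(ev, contaminant_fasta,
                              protease_pattern = "trypsin|lys-?c") {
  fa <- read_fasta_input(contaminant_fasta)
  if (!length(fa$seqs)) {
    warning("empty contaminant database: no precursors flagged")
    return(ev)
  }
  seqs <- chartr("I", "L", toupper(fa$seqs))
  is_prot <- grepl(protease_pattern, fa$headers, ignore.case = TRUE)
  blob_all <- paste(seqs, collapse = "#")
  blob_prot <- paste(seqs[is_prot], collapse = "#")
  peps <- unique(ev$stripped_seq)
  in_blob <- function(p, blob) {
    if (!nzchar(blob)) return(logical(length(p)))
    vapply(p, function(x) grepl(x, blob, fixed = TRUE), TRUE, USE.NAMES = FALSE)
  }
  cont <- peps[in_blob(peps, blob_all)]
  prot <- peps[in_blob(peps, blob_prot)]
  ev[, is_contaminant := stripped_seq %in% cont]
  ev[, is_protease := stripped_seq %in% prot]
  ev[]
}

# Substring-search index over the gapless database: all (species, gene)
# gapless sequences concatenated with '#' separators, plus per-entry global
# sites of each residue.
build_match_index <- function(db, index, residue_maps = NULL) {
  residue_maps <- residue_maps %||% build_residue_maps(db, index)
  entries <- list(); k <- 0L
  for (sp in db$species) {
    for (g in names(residue_maps[[sp]])) {
      a <- db$alignments[[g]][[sp]]
      gapless <- gsub(GAP, "", a, fixed = TRUE)
      if (!nzchar(gapless)) next
      k <- k + 1L
      entries[[k]] <- list(species = sp, gene = g, seq = gapless,
                           sites = residue_maps[[sp]][[g]])
    }
  }
  seqs <- vapply(entries, `[[`, "", "seq")
  lens <- nchar(seqs)
  starts <- cumsum(c(1L, head(lens + 1L, -1L)))  # '#' separators
  structure(list(
    blob = paste(seqs, collapse = "#"),
    species = vapply(entries, `[[`, "", "species"),
    gene = vapply(entries, `[[`, "", "gene"),
    starts = starts, lens = lens,
    sites = lapply(entries, `[[`, "sites")
  ), class = "match_index")
}

#' Annotate peptides against the target+decoy database
#'
#' Finds every exact substring occurrence of each peptide in the gapless
#' sequences of every species (I->L applied on both sides) and lifts the
#' matched residues into global sites through the residue maps.
#'
#' @param peptides Character vector of stripped peptide sequences.
#' @param match_index A `match_index` (built internally by
#'   [build_reference()]).
#' @return A `data.table` with one row per matched residue: `peptide`,
#'   `species`, `gene`, `pos` (1-based residue in the gapless sequence),
#'   `site`, `aa`. Peptides without any match are absent.
#' @export
annotate_peptides <- function(peptides, match_index) {
  peptides <- unique(peptides)
  out <- vector("list", length(peptides))
  bounds <- c(match_index$starts, nchar(match_index$blob) + 2L)
  for (i in seq_along(peptides)) {
    p <- peptides[i]
    hits <- gregexpr(p, match_index$blob, fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    np <- nchar(p)
    aa <- strsplit(p, "")[[1]]
    rows <- lapply(as.integer(hits), function(h) {
      e <- findInterval(h, bounds)
      pos0 <- h - match_index$starts[e]  # 0-based residue offset
      pos <- (pos0 + 1L):(pos0 + np)
      data.table::data.table(
        peptide = p, species = match_index$species[e],
        gene = match_index$gene[e], pos = pos,
        site = match_index$sites[[e]][pos], aa = aa)
    })
    out[[i]] <- data.table::rbindlist(rows)
  }
  res <- data.table::rbindlist(out[!vapply(out, is.null, TRUE)])
  if (!nrow(res)) {
    res <- data.table::data.table(peptide = character(), species = character(),
                                  gene = character(), pos = integer(),
                                  site = integer(), aa = character())
  }
  res[]
}

#' Annotate evidence records with species matches
#'
#' Runs [annotate_peptides()] over the unique non-protease stripped
#' sequences of an evidence table. Unmatched records are kept (they count
#' towards total intensity); protease-flagged records are never annotated.
#'
#' @param ev Evidence `data.table` (after [flag_contaminants()]).
#' @param reference A `species_reference` from [build_reference()].
#' @return List with `evidence` (the table with an added `matched` flag)
#'   and `hits` (the per-residue match table from [annotate_peptides()]).
#' @export
annotate_evidence <- function(ev, reference) {
  peps <- unique(ev$stripped_seq[!ev$is_protease])
  hits <- annotate_peptides(peps, reference$match_index)
  ev[, matched := stripped_seq %in% unique(hits$peptide) & !is_protease]
  list(evidence = ev[], hits = hits)
}

#' Write an evidence table in a search-engine dialect
#'
#' Emits the internal evidence schema with the column names of the chosen
#' dialect, so the file round-trips through [read_evidence()]. Modification
#' notation follows the dialect: MaxQuant-style `_PEPT(de)IDE_` strings are
#' converted to Spectronaut-style `PEPT[Deamidated (NQ)]IDE` for the report
#' dialect.
#'
#' @param ev Evidence `data.table`.
#' @param path Output TSV path.
#' @param dialect Target dialect.
#' @return The path, invisibly.
#' @export
write_evidence <- function(ev, path, dialect = c("maxquant_evidence",
                                                 "spectronaut_report")) {
  dialect <- match.arg(dialect)
  map <- evidence_dialects()[[dialect]]
  mod <- ev$modified_seq
  if (dialect == "spectronaut_report") {
    mod <- gsub("(de)", "[Deamidated (NQ)]", gsub("^_|_$", "", mod),
                fixed = TRUE)
  }
  out <- data.table::data.table(
    a = ev$raw_file, b = ev$stripped_seq, c = mod,
    d = ev$charge, e = ev$intensity, f = ev$score)
  nm <- unname(map[c("raw_file", "stripped_seq", "modified_seq", "charge",
                     "intensity", "score")])
  data.table::setnames(out, nm)
  if (!is.na(map[["precursor_q"]])) {
    out[[map[["precursor_q"]]]] <- ifelse(is.na(ev$precursor_q), 0,
                                          ev$precursor_q)
  }
  out[[map[["proteins"]]]] <- ""
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
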