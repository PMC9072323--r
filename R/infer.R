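#' Infer species for every raw file of a study
#'
#' The main fitting function. Takes the precursor evidence of all raw
#' files of a study (processed jointly, so the decoy q-value is calibrated
#' on the whole cohort), maps peptides to global sites, computes J-scores,
#' decides all species-to-species comparisons per file, refines best
#' matches by marker fine-grouping, and applies the two FDR controls: the
#' blank-calibrated relative protease intensity cutoff (`signal_too_low`)
#' and the coverage-ranked decoy q-value (`above_fdr_threshold`).
#'
#' @param evidence Evidence `data.table` from [read_evidence()] /
#'   [simulate_evidence()], or a list of such tables (concatenated).
#' @param reference A `species_reference` from [build_reference()].
#' @param annotations `data.frame` with columns `raw_file`, `is_blank`
#'   marking laboratory blanks. Files absent from it are treated as
#'   samples.
#' @param contaminants Optional contaminant FASTA (path or text) for
#'   [flag_contaminants()]; skip if the evidence already carries flags.
#' @param markers Optional marker table ([read_marker_table()]).
#' @param fdr_alpha Precursor q-value threshold (default 0.01).
#' @param q_threshold Species-level q-value threshold (default 0.01).
#' @param protease_cutoff_value Manual protease-intensity cutoff;
#'   required when `annotations` contains no blanks.
#' @param mixed_as_target Count a best match mixing targets and decoys as
#'   a target identification for the q-value (default `TRUE`).
#' @return Object of class `species_inference`; see
#'   [print.species_inference()], [summary.species_inference()],
#'   [as.data.frame.species_inference()], [plot.species_inference()] and
#'   [write_results()].
#' @export
infer_species <- function(evidence, reference, annotations = NULL,
                          contaminants = NULL, markers = NULL,
                          fdr_alpha = 0.01, q_threshold = 0.01,
                          protease_cutoff_value = NULL,
                          mixed_as_target = TRUE) {
  if (is.list(evidence) && !is.data.frame(evidence)) {
    evidence <- data.table::rbindlist(evidence, use.names = TRUE)
  }
  ev <- data.table::as.data.table(evidence)
  if (!nrow(ev)) stop("empty evidence: nothing to infer")
  ev <- filter_precursor_fdr(ev, fdr_alpha)
  if (!is.null(contaminants)) ev <- flag_contaminants(ev, contaminants)
  if (!is.null(markers)) markers <- read_marker_table(markers, reference$db)

  files <- sort(unique(ev$raw_file))
  is_blank <- setNames(rep(FALSE, length(files)), files)
  if (!is.null(annotations)) {
    ann <- as.data.frame(annotations)
    hit <- intersect(files, ann$raw_file)
    is_blank[hit] <- as.logical(ann$is_blank[match(hit, ann$raw_file)])
  }

  # protease-intensity QC and blank calibration
  rel_prot <- vapply(files, function(f) relative_protease_intensity(ev, f), 0)
  cutoff <- if (!is.null(protease_cutoff_value)) protease_cutoff_value
            else protease_cutoff(rel_prot[is_blank])
  signal_too_low <- rel_prot >= cutoff

  annotated <- annotate_evidence(ev, reference)
  scores <- score_sites(aggregate_sites(annotated))
  data.table::setkey(scores, raw_file)

  species <- reference$db$species
  is_decoy <- reference$db$is_decoy
  best_list <- fine_list <- vector("list", length(files))
  n_wins <- integer(length(files))
  for (i in seq_along(files)) {
    f <- files[i]
    fs <- scores[data.table::J(f), nomatch = NULL]
    cm <- compete(fs, reference$diff, species)
    bm <- best_match(cm)
    n_wins[i] <- max(competition_wins(cm))
    best_list[[i]] <- bm
    fine_list[[i]] <- if (is.null(markers)) bm
                      else fine_group(ev, markers, bm, f)
  }
  final_list <- fine_list

  sc <- vapply(seq_along(files), function(i) {
    fs <- scores[data.table::J(files[i]), nomatch = NULL]
    site_count(fs, final_list[[i]], reference)
  }, 0L)

  decoy_only <- vapply(final_list, function(s) {
    length(s) > 0 && if (mixed_as_target) all(is_decoy[s]) else any(is_decoy[s])
  }, TRUE)

  deam <- t(vapply(files, function(f) deamidation_fractions(ev, f),
                   c(N = 0, Q = 0)))

  results <- data.frame(
    raw_file = files,
    species = vapply(final_list, paste, "", collapse = ";"),
    best_match = vapply(best_list, paste, "", collapse = ";"),
    n_species = lengths(final_list),
    decoy_only = decoy_only,
    site_count = sc,
    rel_protease_intensity = unname(rel_prot),
    deamidation_N = unname(deam[, "N"]),
    deamidation_Q = unname(deam[, "Q"]),
    is_blank = unname(is_blank),
    signal_too_low = unname(signal_too_low),
    stringsAsFactors = FALSE
  )
  results <- compute_qvalues(results, q_threshold)
  results$flags <- apply(results[, c("signal_too_low", "above_fdr_threshold",
                                     "is_blank")], 1L, function(r) {
    paste(c("signal_too_low", "above_fdr_threshold",
            "blank")[as.logical(r)], collapse = ",")
  })
  rownames(results) <- NULL

  structure(list(
    results = results,
    site_scores = scores,
    reference = reference,
    params = list(fdr_alpha = fdr_alpha, q_threshold = q_threshold,
                  protease_cutoff = unname(cutoff),
                  mixed_as_target = mixed_as_target,
                  n_files = length(files)),
    evidence = ev
  ), class = "species_inference")
}

#' @export
print.species_inference <- function(x, ...) {
  r <- x$results
  pass <- !r$signal_too_low & !r$above_fdr_threshold
  cat("Species inference\n")
  cat(sprintf("  %d raw files (%d blanks); protease-intensity cutoff %.4g\n",
              nrow(r), sum(r$is_blank), x$params$protease_cutoff))
  cat(sprintf("  %d passed both thresholds, %d flagged signal_too_low, %d above %g%% species FDR\n",
              sum(pass), sum(r$signal_too_low), sum(r$above_fdr_threshold),
              100 * x$params$q_threshold))
  if (any(pass)) {
    cat(sprintf("  passing files: site count %d-%d, %d decoy-only assignment(s)\n",
                min(r$site_count[pass]), max(r$site_count[pass]),
                sum(r$decoy_only[pass])))
  }
  invisible(x)
}

#' @export
#' @method summary species_inference
summary.species_inference <- function(object, ...) {
  r <- object$results
  pass <- !r$signal_too_low & !r$above_fdr_threshold
  tab <- sort(table(r$species[pass & !r$decoy_only]), decreasing = TRUE)
  out <- list(n_files = nrow(r), n_pass = sum(pass),
              n_signal_too_low = sum(r$signal_too_low),
              n_above_fdr = sum(r$above_fdr_threshold),
              decoy_only_pct = if (any(pass))
                100 * mean(r$decoy_only[pass]) else NA_real_,
              species_table = tab,
              protease_cutoff = object$params$protease_cutoff)
  class(out) <- "summary.species_inference"
  out
}

#' @export
print.summary.species_inference <- function(x, ...) {
  cat(sprintf("%d files: %d pass, %d signal too low, %d above species FDR\n",
              x$n_files, x$n_pass, x$n_signal_too_low, x$n_above_fdr))
  cat(sprintf("decoy-only among passing: %.2f%%\n", x$decoy_only_pct))
  cat("species assignments (passing files):\n")
  print(x$species_table)
  invisible(x)
}

#' @export
as.data.frame.species_inference <- function(x, ...) x$results

#' Coverage vs. protease-intensity QC plot
#'
#' Scatter of site count against relative protease intensity (reversed
#' log10 axis: low-signal files sit at the bottom), with the two cutoffs
#' drawn; blanks are shown as filled black points.
#'
#' @param x A `species_inference`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.species_inference <- function(x, ...) {
  r <- x$results
  eps <- 1e-4
  y <- -log10(pmax(r$rel_protease_intensity, eps))
  graphics::plot(r$site_count, y,
                 pch = ifelse(r$is_blank, 19, 1),
                 col = ifelse(r$above_fdr_threshold, "#c04070", "#305080"),
                 xlab = "site count (absolute sequence coverage)",
                 ylab = "-log10 relative protease intensity", ...)
  graphics::abline(h = -log10(pmax(x$params$protease_cutoff, eps)), lty = 2)
  passing <- r$site_count[!r$above_fdr_threshold & !r$signal_too_low]
  if (length(passing)) graphics::abline(v = min(passing), lty = 3)
  invisible(x)
}

#' Write the global result table and companion outputs
#'
#' Writes the per-file result table (TSV), a QC metrics table (TSV), and
#' the per-sample consensus sequences (FASTA) into a directory, plus a
#' machine-readable provenance record (JSON) with parameters and file
#' checksums.
#'
#' @param x A `species_inference`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_results <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res_path <- file.path(dir, "species_results.tsv")
  qc_path <- file.path(dir, "qc_metrics.tsv")
  cons_path <- file.path(dir, "consensus.fasta")
  data.table::fwrite(x$results, res_path, sep = "\t")
  qc <- x$results[, c("raw_file", "site_count", "rel_protease_intensity",
                      "deamidation_N", "deamidation_Q", "q_value", "flags")]
  data.table::fwrite(qc, qc_path, sep = "\t")
  write_consensus_fasta(x$site_scores, x$reference, cons_path)
  prov <- list(params = x$params,
               files = as.list(tools::md5sum(c(res_path, qc_path, cons_path))))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
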