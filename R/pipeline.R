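#' Read and validate a run configuration
#'
#' The run configuration is a YAML file with two top-level maps: `paths`
#' (`database`, `contaminants`, `markers`, `evidence` (file or directory),
#' `annotations`, `output`) and `params` (`gene_set`, `max_missing`,
#' `slice_len`, `n_decoys`, `fdr_alpha`, `q_threshold`,
#' `protease_cutoff`, `dialect`, `seed`). Every parameter has a default;
#' referenced input paths must exist.
#'
#' @param path YAML file path, or a list with the same structure.
#' @return Validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  cfg$paths <- cfg$paths %||% list()
  defaults <- list(gene_set = bone_gene_set(), max_missing = 5L,
                   slice_len = 500L, n_decoys = NULL, fdr_alpha = 0.01,
                   q_threshold = 0.01, protease_cutoff = NULL,
                   dialect = "maxquant_evidence", seed = 1L)
  cfg$params <- utils::modifyList(defaults, cfg$params %||% list())
  if (!(cfg$params$dialect %in% names(evidence_dialects()))) {
    stop("unknown evidence dialect: ", cfg$params$dialect)
  }
  for (p in c("fdr_alpha", "q_threshold")) {
    v <- cfg$params[[p]]
    if (v < 0 || v > 1) stop(p, " must be in [0, 1]")
  }
  for (nm in c("database", "contaminants", "markers", "evidence",
               "annotations")) {
    p <- cfg$paths[[nm]]
    if (!is.null(p) && !file.exists(p)) {
      stop("configured path does not exist: ", nm, " = ", p)
    }
  }
  structure(cfg, class = "run_config")
}

write_provenance <- function(dir, cfg, artifacts) {
  prov <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    params = cfg$params[!vapply(cfg$params, is.null, TRUE)],
    checksums = as.list(tools::md5sum(artifacts[file.exists(artifacts)]))
  )
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Build and persist the reference artifacts
#'
#' Parses the configured database FASTA, applies the gene-count filter,
#' generates decoys with the configured seed, and writes the combined
#' target+decoy database (aligned and gapless FASTA), the decoy
#' provenance, the removal report, a difference-matrix summary, and a
#' provenance record into the output directory.
#'
#' @param cfg A `run_config` (its `paths$database` must be set).
#' @param out_dir Output directory; default `paths$output`.
#' @return The `species_reference`, invisibly.
#' @export
cmd_build_db <- function(cfg, out_dir = cfg$paths$output) {
  cfg <- read_run_config(cfg)
  if (is.null(cfg$paths$database)) stop("config lacks paths$database")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- build_reference(cfg$paths$database, gene_set = cfg$params$gene_set,
                         max_missing = cfg$params$max_missing,
                         n_decoys = cfg$params$n_decoys,
                         slice_len = cfg$params$slice_len,
                         seed = cfg$params$seed)
  aligned <- file.path(out_dir, "database_td_aligned.fasta")
  gapless <- file.path(out_dir, "database_td_gapless.fasta")
  write_database_fasta(ref$db, aligned, gapless = FALSE)
  write_database_fasta(ref$db, gapless, gapless = TRUE)
  prov_tsv <- file.path(out_dir, "decoy_provenance.tsv")
  data.table::fwrite(ref$db$decoy_provenance, prov_tsv, sep = "\t")
  removed <- file.path(out_dir, "removed_species.tsv")
  data.table::fwrite(ref$db$removed %||%
                       data.frame(species = character(),
                                  genes_present = integer()),
                     removed, sep = "\t")
  diffsum <- ref$diff[, list(n_sites = .N), by = c("species_a", "species_b")]
  diff_tsv <- file.path(out_dir, "difference_matrix_summary.tsv")
  data.table::fwrite(diffsum, diff_tsv, sep = "\t")
  writeLines(c(sprintf("L\t%d", ref$index$L),
               sprintf("targets\t%d", sum(!ref$db$is_decoy)),
               sprintf("decoys\t%d", sum(ref$db$is_decoy))),
             file.path(out_dir, "build_summary.tsv"))
  write_provenance(out_dir, cfg, c(aligned, gapless, prov_tsv, diff_tsv))
  invisible(ref)
}

#' Run the inference on configured evidence tables
#'
#' Loads all evidence tables (a file or every `*.tsv` in a directory) in
#' the configured dialect, the sample annotations (TSV with `raw_file`,
#' `is_blank`), optional contaminants and markers, rebuilds the reference
#' from the persisted target+decoy FASTA (decoys recognized by name
#' prefix), runs [infer_species()] over all files jointly, and writes the
#' result artifacts via [write_results()].
#'
#' @param cfg A `run_config`; `paths$database` may point at the
#'   `database_td_aligned.fasta` written by [cmd_build_db()].
#' @param out_dir Output directory.
#' @return The `species_inference`, invisibly.
#' @export
cmd_infer <- function(cfg, out_dir = cfg$paths$output) {
  cfg <- read_run_config(cfg)
  ev_path <- cfg$paths$evidence
  if (is.null(ev_path)) stop("config lacks paths$evidence")
  files <- if (dir.exists(ev_path)) {
    list.files(ev_path, pattern = "\\.tsv$", full.names = TRUE)
  } else ev_path
  if (!length(files)) stop("no evidence tables found under ", ev_path)
  ev <- data.table::rbindlist(
    lapply(files, read_evidence, dialect = cfg$params$dialect))
  ref <- build_reference(cfg$paths$database, gene_set = cfg$params$gene_set,
                         max_missing = cfg$params$max_missing,
                         add_decoys = FALSE, seed = cfg$params$seed)
  if (!any(ref$db$is_decoy)) {
    index <- build_global_index(ref$db)
    ref <- build_reference(
      generate_decoys(ref$db, index, slice_len = cfg$params$slice_len,
                      n_decoys = cfg$params$n_decoys,
                      seed = cfg$params$seed),
      max_missing = Inf, add_decoys = FALSE)
  }
  ann <- if (!is.null(cfg$paths$annotations)) {
    utils::read.delim(cfg$paths$annotations, stringsAsFactors = FALSE)
  } else NULL
  fit <- infer_species(ev, ref, annotations = ann,
                       contaminants = cfg$paths$contaminants,
                       markers = cfg$paths$markers,
                       fdr_alpha = cfg$params$fdr_alpha,
                       q_threshold = cfg$params$q_threshold,
                       protease_cutoff_value = cfg$params$protease_cutoff)
  write_results(fit, out_dir)
  write_provenance(out_dir, cfg,
                   file.path(out_dir, c("species_results.tsv",
                                        "qc_metrics.tsv",
                                        "consensus.fasta")))
  invisible(fit)
}

#' Simulate a study to disk
#'
#' Generates a synthetic database and evidence with [simulate_database()]
#' and [simulate_evidence()], and writes everything a subsequent
#' `build-db` + `infer` run needs: the target database FASTA, evidence
#' TSVs in both dialects, the sample-annotation TSV, and the
#' configuration used.
#'
#' @param cfg A `run_config`; `params` entries matching [sim_config()]
#'   arguments are forwarded to the simulator.
#' @param out_dir Output directory.
#' @return The output directory, invisibly.
#' @export
cmd_simulate <- function(cfg, out_dir = cfg$paths$output) {
  cfg <- read_run_config(cfg)
  sim_args <- cfg$params[intersect(names(cfg$params),
                                   names(formals(sim_config)))]
  scfg <- do.call(sim_config, sim_args)
  simdb <- simulate_database(scfg)
  n_samples <- cfg$params$n_samples %||% 10L
  sim <- simulate_evidence(simdb, scfg,
                           plan = with_seed(scfg$seed,
                             study_plan(simdb, n_samples = n_samples,
                                        n_blanks = scfg$n_blanks)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  db_fa <- file.path(out_dir, "database_targets.fasta")
  write_database_fasta(simdb, db_fa)
  mq <- file.path(out_dir, "evidence_maxquant.tsv")
  sn <- file.path(out_dir, "evidence_spectronaut.tsv")
  write_evidence(sim$evidence, mq, "maxquant_evidence")
  write_evidence(sim$evidence, sn, "spectronaut_report")
  ann <- file.path(out_dir, "annotations.tsv")
  data.table::fwrite(sim$annotations, ann, sep = "\t")
  yaml::write_yaml(list(params = cfg$params), file.path(out_dir, "config.yaml"))
  write_provenance(out_dir, cfg, c(db_fa, mq, sn, ann))
  invisible(out_dir)
}
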