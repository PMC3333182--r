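#' Pipeline run configuration
#'
#' Bundles input locations, thresholds, species metadata and the seed for a
#' full catalogue-to-report run. All inputs are optional: with no catalogue
#' the packaged study fixtures are analysed; alignment and structure stages
#' run only when their inputs are present. The configuration round-trips
#' through YAML unchanged.
#'
#' @param catalogue Path to a catalogue TSV, a catalogue data.frame, or NULL
#'   for the packaged fixture.
#' @param alignment Path to a Clustal/aligned-FASTA profile alignment, or
#'   NULL.
#' @param structure Path to a PDB coordinate file, or NULL.
#' @param out_dir Output directory for the report bundle.
#' @param seed Integer seed recorded in the bundle (used by any stage that
#'   draws random numbers).
#' @param config A [severity_config()].
#' @param extrapolate_to Species to extrapolate mutations into (used when an
#'   alignment is supplied).
#' @return A list of class `run_config`.
#' @export
run_config <- function(catalogue = NULL, alignment = NULL, structure = NULL,
                       out_dir = tempfile("manba_run_"), seed = 1L,
                       config = severity_config(),
                       extrapolate_to = "mouse") {
  stopifnot(inherits(config, "severity_config"))
  structure(list(catalogue = catalogue, alignment = alignment,
                 structure = structure, out_dir = out_dir,
                 seed = as_scalar_int(seed, "seed"), config = config,
                 extrapolate_to = extrapolate_to),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#' @param rc A [run_config()] (paths only; a data.frame catalogue cannot be
#'   serialized and is rejected).
#' @param path File path.
#' @return `read_run_config` returns a `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
write_run_config <- function(rc, path) {
  stopifnot(inherits(rc, "run_config"))
  abort_if(is.data.frame(rc$catalogue),
           "only path-based configurations can be written to YAML")
  out <- unclass(rc)
  out$config <- unclass(out$config)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  vals$config <- do.call(severity_config, vals$config)
  do.call(run_config, vals)
}

#' Run the full genotype-phenotype pipeline
#'
#' Executes catalogue parsing and summary, protein-consequence translation,
#' severity classification, hot-spot detection and (when an alignment is
#' given) cross-species extrapolation, writing a TSV/JSON report bundle to
#' `out_dir`: `summary.json`, `severity.tsv`, `hotspots.tsv`, optionally
#' `extrapolation.tsv`, and `bundle.json` containing every result table
#' plus the thresholds, seed and package version (full provenance, no
#' timestamps, so reruns are byte-identical).
#'
#' When the catalogue is the packaged fixture, the published substitution
#' evidence, biallelic pairings and hot-spot segments are used; for other
#' catalogues hot-spots are clustered from the records' nucleotide
#' positions with `config$gap_threshold_nt`.
#'
#' @param rc A [run_config()].
#' @return Invisibly, the report bundle (a list).
#' @export
#' @examples
#' bundle <- run_pipeline(run_config(out_dir = tempfile()))
#' bundle$summary$total_distinct
#' nrow(bundle$severity)
run_pipeline <- function(rc = run_config()) {
  stopifnot(inherits(rc, "run_config"))
  fx <- study_fixtures()
  using_fixture <- is.null(rc$catalogue)
  records <- if (using_fixture) {
    fx$catalogue
  } else if (is.data.frame(rc$catalogue)) {
    validate_catalogue(rc$catalogue)
  } else {
    read_catalogue(rc$catalogue)
  }

  summary <- summarize_catalogue(records)

  severity <- tryCatch(
    classify_all(records,
                 evidence = if (using_fixture) fx$substitution_evidence,
                 as_def = fx$active_site, config = rc$config,
                 partners = if (using_fixture) fx$partner_pairs),
    error = function(e) stop("severity stage failed: ",
                             conditionMessage(e), call. = FALSE))

  hotspots <- if (using_fixture) {
    fx$hotspots
  } else {
    pos <- records[!is.na(records$nt_start), c("id", "nt_start")]
    if (nrow(pos) >= 1L) {
      pos <- pos[order(pos$nt_start), ]
      cluster_mutations(data.frame(id = pos$id, nt = pos$nt_start),
                        gap_threshold = rc$config$gap_threshold_nt)
    } else NULL
  }

  extrapolation <- NULL
  if (!is.null(rc$alignment)) {
    aln <- if (inherits(rc$alignment, "profile_alignment")) rc$alignment
           else read_alignment(rc$alignment)
    extrapolation <- tryCatch(
      extrapolate_mutations(records, aln, rc$extrapolate_to),
      error = function(e) stop("extrapolation stage failed: ",
                               conditionMessage(e), call. = FALSE))
  }

  dir.create(rc$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_summary_json(summary, file.path(rc$out_dir, "summary.json"))
  utils::write.table(severity, file.path(rc$out_dir, "severity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(hotspots))
    write_hotspots_tsv(hotspots, file.path(rc$out_dir, "hotspots.tsv"))
  if (!is.null(extrapolation))
    write_mapping_tsv(extrapolation,
                      file.path(rc$out_dir, "extrapolation.tsv"))

  bundle <- list(
    package_version = as.character(utils::packageVersion("manbatools")),
    seed = rc$seed,
    thresholds = unclass(rc$config),
    summary = list(total_distinct = summary$total_distinct,
                   per_species = summary$per_species),
    severity = severity,
    hotspots = if (!is.null(hotspots)) {
      h <- as.data.frame(hotspots)
      h$member_ids <- vapply(h$member_ids, paste, character(1), collapse = ",")
      h
    },
    extrapolation = extrapolation
  )
  jsonlite::write_json(bundle, file.path(rc$out_dir, "bundle.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(bundle)
}
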