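CATALOGUE_COLUMNS <- c("id", "species", "event_kind", "nt_start", "nt_end",
                       "inserted_bases", "deleted_bases", "protein_ref",
                       "protein_pos", "protein_alt", "zygosity",
                       "observed_phenotype", "shared_species", "source_note")

EVENT_KINDS <- c("nonsense", "missense", "insertion", "deletion")
ZYGOSITIES <- c("homozygous", "heterozygous", "compound_heterozygous", "unknown")
PHENOTYPES <- c("mild", "moderate", "severe", "unknown")

#' Parse a protein-level mutation token
#'
#' Splits a token of the form `<ref><position><alt>` (e.g. "W466X", "R182W")
#' into its components. The stop symbol is normalized to 'X' ('*' is accepted
#' on input). Synonymous tokens (ref == alt) are rejected.
#'
#' @param token A single string such as "W466X".
#' @return A list with elements `protein_ref`, `protein_pos`, `protein_alt`.
#' @export
#' @examples
#' parse_protein_notation("W466X")
#' parse_protein_notation("R182W")
parse_protein_notation <- function(token) {
  token <- as_scalar_chr(token)
  m <- regmatches(token, regexec("^([A-Za-z])([0-9]+)([A-Za-z*])$", token))[[1]]
  abort_if(length(m) == 0L,
           sprintf("malformed protein mutation token '%s'", token))
  ref <- toupper(m[2])
  pos <- as.integer(m[3])
  alt <- toupper(m[4])
  if (alt == "*") alt <- STOP_SYMBOL
  abort_if(!ref %in% AA_LETTERS,
           sprintf("unknown reference residue in token '%s'", token))
  abort_if(!alt %in% c(AA_LETTERS, STOP_SYMBOL),
           sprintf("unknown substituted residue in token '%s'", token))
  abort_if(pos < 1L, sprintf("position must be >= 1 in token '%s'", token))
  abort_if(ref == alt,
           sprintf("synonymous token '%s' is not a valid mutation", token))
  list(protein_ref = ref, protein_pos = pos, protein_alt = alt)
}

#' Construct a single mutation record
#'
#' One inherited mutation: a nucleotide-level event on the MANBA coding
#' sequence together with its protein-level consequence, zygosity and the
#' clinically observed phenotype. Protein positions use precursor (signal
#' peptide included) numbering. Nucleotide coordinates are stored verbatim
#' from the source catalogue; their coordinate system is resolved by the
#' transcript's `coord_offset` at analysis time.
#'
#' @param id Unique record identifier.
#' @param species One of "human", "cow", "goat", "mouse".
#' @param event_kind One of "nonsense", "missense", "insertion", "deletion".
#' @param protein A token such as "W466X", or NULL if `protein_ref`,
#'   `protein_pos`, `protein_alt` are given explicitly.
#' @param nt_start,nt_end 1-based inclusive nucleotide coordinates (NA when
#'   unknown).
#' @param inserted_bases,deleted_bases Nucleotide strings for indel events
#'   (NA when the bases are not recorded).
#' @param protein_ref,protein_pos,protein_alt Protein-change components
#'   (ignored when `protein` is given).
#' @param zygosity One of "homozygous", "heterozygous",
#'   "compound_heterozygous", "unknown".
#' @param observed_phenotype One of "mild", "moderate", "severe", "unknown"
#'   ("lethal" ruminant outcomes are recorded as "severe").
#' @param shared_species Character vector of additional species in which the
#'   same mutation has been reported.
#' @param source_note Free-text provenance note.
#' @return A one-row data.frame with the catalogue columns.
#' @export
#' @examples
#' mutation_record("HsW466X", "human", "nonsense", protein = "W466X",
#'                 zygosity = "compound_heterozygous")
mutation_record <- function(id, species, event_kind, protein = NULL,
                            nt_start = NA, nt_end = NA,
                            inserted_bases = NA, deleted_bases = NA,
                            protein_ref = NA, protein_pos = NA,
                            protein_alt = NA,
                            zygosity = "unknown",
                            observed_phenotype = "unknown",
                            shared_species = character(),
                            source_note = NA) {
  if (!is.null(protein)) {
    p <- parse_protein_notation(protein)
    protein_ref <- p$protein_ref
    protein_pos <- p$protein_pos
    protein_alt <- p$protein_alt
  }
  rec <- data.frame(
    id = as_scalar_chr(id),
    species = as_scalar_chr(species),
    event_kind = as_scalar_chr(event_kind),
    nt_start = if (is.na(nt_start)) NA_integer_ else as_scalar_int(nt_start, "nt_start"),
    nt_end = if (is.na(nt_end)) NA_integer_ else as_scalar_int(nt_end, "nt_end"),
    inserted_bases = as.character(inserted_bases),
    deleted_bases = as.character(deleted_bases),
    protein_ref = as.character(protein_ref),
    protein_pos = as.integer(protein_pos),
    protein_alt = as.character(protein_alt),
    zygosity = as_scalar_chr(zygosity),
    observed_phenotype = as_scalar_chr(observed_phenotype),
    shared_species = paste(shared_species, collapse = ","),
    source_note = as.character(source_note),
    stringsAsFactors = FALSE
  )
  validate_catalogue(rec)
  rec
}

#' Validate a mutation catalogue
#'
#' Checks the structural invariants of a catalogue data.frame: enumerated
#' fields, nonsense records ending in the stop symbol, missense records being
#' true substitutions, positive positions, and coordinate ordering.
#'
#' @param records A data.frame with the catalogue columns.
#' @return The validated data.frame, invisibly.
#' @export
validate_catalogue <- function(records) {
  abort_if(!is.data.frame(records), "catalogue must be a data.frame")
  missing <- setdiff(CATALOGUE_COLUMNS, names(records))
  abort_if(length(missing) > 0L,
           "catalogue is missing columns: ", paste(missing, collapse = ", "))
  if (nrow(records) == 0L) return(invisible(records))
  abort_if(anyDuplicated(records$id) > 0L, "duplicate record ids")
  bad_sp <- setdiff(unique(records$species), MANBA_SPECIES)
  abort_if(length(bad_sp) > 0L,
           "unknown species: ", paste(bad_sp, collapse = ", "))
  abort_if(!all(records$event_kind %in% EVENT_KINDS), "invalid event_kind")
  abort_if(!all(records$zygosity %in% ZYGOSITIES), "invalid zygosity")
  abort_if(!all(records$observed_phenotype %in% PHENOTYPES),
           "invalid observed_phenotype")
  abort_if(any(records$protein_pos < 1L, na.rm = TRUE),
           "protein_pos must be >= 1")
  ok_nt <- is.na(records$nt_start) | is.na(records$nt_end) |
    records$nt_end >= records$nt_start
  abort_if(!all(ok_nt), "nt_end must be >= nt_start")
  ns <- records$event_kind == "nonsense"
  abort_if(!all(records$protein_alt[ns] == STOP_SYMBOL, na.rm = TRUE),
           "nonsense records must have protein_alt 'X'")
  ms <- records$event_kind == "missense"
  abort_if(any(records$protein_alt[ms] == STOP_SYMBOL, na.rm = TRUE),
           "missense records must not introduce a stop")
  abort_if(any(records$protein_alt[ms] == records$protein_ref[ms],
               na.rm = TRUE),
           "missense records must change the residue")
  invisible(records)
}

#' Is an indel record frameshifting?
#'
#' An insertion or deletion shifts the reading frame when the number of bases
#' involved is not divisible by 3. The base count is taken from the recorded
#' bases when present, otherwise inferred from the nucleotide interval (for an
#' insertion reported as an interval, `nt_end - nt_start` bases are inserted;
#' a deletion spans `nt_end - nt_start + 1` bases). Returns NA when the count
#' cannot be determined; substitutions return FALSE.
#'
#' @param records A catalogue data.frame.
#' @return Logical vector, one element per record.
#' @export
is_frameshift <- function(records) {
  n <- nrow(records)
  out <- rep(FALSE, n)
  for (i in seq_len(n)) {
    kind <- records$event_kind[i]
    if (kind == "insertion") {
      len <- if (!is.na(records$inserted_bases[i]))
        nchar(records$inserted_bases[i])
      else if (!is.na(records$nt_start[i]) && !is.na(records$nt_end[i]))
        records$nt_end[i] - records$nt_start[i]
      else NA_integer_
      out[i] <- if (is.na(len)) NA else (len %% 3L != 0L)
    } else if (kind == "deletion") {
      len <- if (!is.na(records$deleted_bases[i]))
        nchar(records$deleted_bases[i])
      else if (!is.na(records$nt_start[i]) && !is.na(records$nt_end[i]))
        records$nt_end[i] - records$nt_start[i] + 1L
      else NA_integer_
      out[i] <- if (is.na(len)) NA else (len %% 3L != 0L)
    }
  }
  out
}

#' Classify the protein-level consequence of each record
#'
#' Nonsense mutations truncate the chain; insertions and deletions truncate
#' when they shift the reading frame or directly introduce a stop; missense
#' mutations are substitutions. Indels whose frame status cannot be
#' determined are called truncating (conservative call).
#'
#' @param records A catalogue data.frame.
#' @return Character vector of "truncating" / "substitution".
#' @export
#' @examples
#' cat15 <- manba_catalogue()
#' table(classify_consequence(cat15), cat15$species)
classify_consequence <- function(records) {
  validate_catalogue(records)
  fs <- is_frameshift(records)
  out <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    kind <- records$event_kind[i]
    if (kind == "nonsense") {
      out[i] <- "truncating"
    } else if (kind == "missense") {
      out[i] <- "substitution"
    } else {
      stop_introduced <- !is.na(records$protein_alt[i]) &&
        records$protein_alt[i] == STOP_SYMBOL
      out[i] <- if (isTRUE(fs[i]) || is.na(fs[i]) || stop_introduced)
        "truncating" else "substitution"
    }
  }
  out
}

#' Summarize a mutation catalogue
#'
#' Per-species counts of truncating and substitution mutations and the
#' percentage of truncating cases (rounded to one decimal). An empty
#' catalogue yields an all-zero summary.
#'
#' @param records A catalogue data.frame.
#' @return An object of class `catalogue_summary`: a list with
#'   `total_distinct` and a `per_species` data.frame.
#' @export
#' @examples
#' summarize_catalogue(manba_catalogue())
summarize_catalogue <- function(records) {
  validate_catalogue(records)
  if (nrow(records) == 0L) {
    per <- data.frame(species = character(), total = integer(),
                      truncating = integer(), substitution = integer(),
                      percent_truncating = numeric(),
                      stringsAsFactors = FALSE)
    return(structure(list(total_distinct = 0L, per_species = per),
                     class = "catalogue_summary"))
  }
  cons <- classify_consequence(records)
  species <- sort(unique(records$species))
  per <- do.call(rbind, lapply(species, function(sp) {
    sel <- records$species == sp
    tr <- sum(cons[sel] == "truncating")
    su <- sum(cons[sel] == "substitution")
    data.frame(species = sp, total = sum(sel), truncating = tr,
               substitution = su,
               percent_truncating = round(100 * tr / sum(sel), 1),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  structure(list(total_distinct = nrow(records), per_species = per),
            class = "catalogue_summary")
}

#' @export
print.catalogue_summary <- function(x, ...) {
  cat("Mutation catalogue:", x$total_distinct, "distinct records\n")
  print(x$per_species, row.names = FALSE)
  invisible(x)
}

#' Write / read the catalogue TSV dialect
#'
#' One record per line, header row, columns in the canonical field order,
#' '.' for missing values, UTF-8. `shared_species` is comma-separated.
#'
#' @param records A catalogue data.frame.
#' @param path File path.
#' @return `read_catalogue` returns the catalogue data.frame;
#'   `write_catalogue` returns `path` invisibly.
#' @export
write_catalogue <- function(records, path) {
  validate_catalogue(records)
  out <- records[, CATALOGUE_COLUMNS, drop = FALSE]
  for (cn in names(out)) {
    v <- as.character(out[[cn]])
    v[is.na(v) | v == ""] <- "."
    out[[cn]] <- v
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_catalogue
#' @export
read_catalogue <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  missing <- setdiff(CATALOGUE_COLUMNS, names(raw))
  abort_if(length(missing) > 0L,
           "catalogue file missing columns: ", paste(missing, collapse = ", "))
  raw[raw == "."] <- NA
  for (cn in c("nt_start", "nt_end", "protein_pos"))
    raw[[cn]] <- as.integer(raw[[cn]])
  raw$shared_species[is.na(raw$shared_species)] <- ""
  raw$protein_alt[!is.na(raw$protein_alt) & raw$protein_alt == "*"] <- STOP_SYMBOL
  validate_catalogue(raw)
  raw
}

#' Export a catalogue summary as JSON
#'
#' @param summary A `catalogue_summary`.
#' @param path File path for the JSON output.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  stopifnot(inherits(summary, "catalogue_summary"))
  jsonlite::write_json(
    list(total_distinct = summary$total_distinct,
         per_species = summary$per_species),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
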