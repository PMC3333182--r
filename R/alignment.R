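#' ClustalX amino-acid conservation groups
#'
#' The strong and weak residue groups of the ClustalX/ClustalW annotation
#' convention: a fully identical column is marked '*', a column whose
#' residues all fall in one strong group ':' (conservative substitution),
#' one weak group '.' (semi-conservative), otherwise unmarked. Stored as
#' configuration data so the convention is inspectable and replaceable.
#'
#' @return List with character vectors `strong` and `weak`.
#' @export
conservation_groups <- function() {
  list(
    strong = c("STA", "NEQK", "NHQK", "NDEQ", "QHRK", "MILV", "MILF", "HY",
               "FYW"),
    weak = c("CSA", "ATV", "SAG", "STNK", "STPA", "SGND", "SDEQN", "NDEQHK",
             "NEQHRK", "FVLIM", "HFY")
  )
}

#' Profile alignment container
#'
#' An ordered set of equal-length gapped amino-acid sequences keyed by
#' species label. Ungapping a row yields that species' mature (signal
#' peptide excised) sequence.
#'
#' @param rows Named character vector of gapped sequences (gap character
#'   '-').
#' @return An object of class `profile_alignment`.
#' @export
#' @examples
#' profile_alignment(c(human = "MW-D", goat = "MWAD"))
profile_alignment <- function(rows) {
  abort_if(is.null(names(rows)) || any(names(rows) == ""),
           "alignment rows must be named by species")
  rows <- toupper(vapply(rows, as.character, character(1)))
  widths <- nchar(rows)
  abort_if(length(unique(widths)) != 1L,
           "ragged alignment: rows have unequal lengths (",
           paste(widths, collapse = ", "), ")")
  for (i in seq_along(rows)) {
    bad <- regexpr(sprintf("[^%s-]", paste(AA_LETTERS, collapse = "")), rows[[i]])
    abort_if(bad > 0L,
             sprintf("unknown character '%s' in alignment row %d ('%s') at column %d",
                     substr(rows[[i]], bad, bad), i, names(rows)[i], bad))
  }
  structure(list(rows = rows, ncol = unname(widths[1L])),
            class = "profile_alignment")
}

#' @export
print.profile_alignment <- function(x, ...) {
  cat("Profile alignment:", length(x$rows), "rows x", x$ncol, "columns\n")
  for (nm in names(x$rows))
    cat(sprintf("  %-10s %s\n", nm,
                if (x$ncol > 60) paste0(substr(x$rows[[nm]], 1, 57), "...")
                else x$rows[[nm]]))
  invisible(x)
}

#' Read a profile alignment from Clustal or aligned-FASTA format
#'
#' Format is detected from the file header (a leading CLUSTAL line selects
#' Clustal format). Parsing is delegated to
#' `Biostrings::readAAMultipleAlignment()`.
#'
#' @param path Path to the alignment file.
#' @return A [profile_alignment()].
#' @export
read_alignment <- function(path) {
  abort_if(!file.exists(path), "alignment file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  fmt <- if (length(first) && grepl("^CLUSTAL", first, ignore.case = TRUE))
    "clustal" else "fasta"
  aln <- tryCatch(
    Biostrings::readAAMultipleAlignment(path, format = fmt),
    error = function(e) stop("failed to parse alignment '", path, "' (",
                             fmt, " format): ", conditionMessage(e),
                             call. = FALSE))
  rows <- as.character(aln)
  profile_alignment(rows)
}

aln_row <- function(aln, species) {
  stopifnot(inherits(aln, "profile_alignment"))
  abort_if(!species %in% names(aln$rows),
           sprintf("species '%s' not present in alignment (rows: %s)",
                   species, paste(names(aln$rows), collapse = ", ")))
  strsplit(aln$rows[[species]], "")[[1]]
}

#' Ungapped length of an alignment row
#' @param aln A [profile_alignment()].
#' @param species Row label.
#' @return Integer number of residues.
#' @export
ungapped_length <- function(aln, species) {
  sum(aln_row(aln, species) != "-")
}

#' Excise the signal peptide from a precursor sequence
#'
#' Removes the N-terminal signal peptide (17 residues; 19 in mouse), giving
#' the mature sequence. Mature position = precursor position - signal
#' length.
#'
#' @param seq Precursor amino-acid sequence.
#' @param species Species label (sets the default signal length).
#' @param signal_len Override for the signal-peptide length.
#' @return The mature sequence.
#' @export
#' @examples
#' trim_signal_peptide(strrep("A", 30), "human")  # 13 residues remain
trim_signal_peptide <- function(seq, species, signal_len = NULL) {
  seq <- toupper(as_scalar_chr(seq))
  if (is.null(signal_len)) signal_len <- signal_length(species)
  abort_if(nchar(seq) <= signal_len,
           sprintf("sequence of length %d is not longer than the %d-residue signal peptide",
                   nchar(seq), signal_len))
  substr(seq, signal_len + 1L, nchar(seq))
}

#' Map a residue position across species through the alignment
#'
#' Finds the alignment column holding residue `pos` of the source row and
#' returns the target row's ungapped index at that column, or NA when the
#' target is gapped there. Positions are 1-based on the ungapped (mature)
#' sequences.
#'
#' @param aln A [profile_alignment()].
#' @param from_species,to_species Row labels.
#' @param pos Residue position in the source row.
#' @return Integer position or NA, with attribute `column` (the alignment
#'   column used).
#' @export
map_position <- function(aln, from_species, pos, to_species) {
  src <- aln_row(aln, from_species)
  pos <- as_scalar_int(pos, "pos")
  src_idx <- which(src != "-")
  abort_if(pos < 1L || pos > length(src_idx),
           sprintf("position %d outside the ungapped length (%d) of row '%s'",
                   pos, length(src_idx), from_species))
  col <- src_idx[pos]
  tgt <- aln_row(aln, to_species)
  out <- if (tgt[col] == "-") NA_integer_ else sum(tgt[seq_len(col)] != "-")
  attr(out, "column") <- col
  out
}

#' Conservation class of an alignment column
#'
#' 'identical' when all rows carry the same residue (no gaps); otherwise
#' 'conservative' / 'semi_conservative' when every residue in the column
#' falls within a single strong / weak ClustalX group; 'non_conserved'
#' otherwise (gapped columns are non-conserved).
#'
#' @param aln A [profile_alignment()].
#' @param column Column index.
#' @param groups Group tables, as from [conservation_groups()].
#' @return One of "identical", "conservative", "semi_conservative",
#'   "non_conserved".
#' @export
column_conservation <- function(aln, column, groups = conservation_groups()) {
  stopifnot(inherits(aln, "profile_alignment"))
  column <- as_scalar_int(column, "column")
  abort_if(column < 1L || column > aln$ncol,
           sprintf("column %d outside alignment width %d", column, aln$ncol))
  chars <- vapply(names(aln$rows),
                  function(sp) aln_row(aln, sp)[column], character(1))
  if (any(chars == "-")) return("non_conserved")
  uniq <- unique(chars)
  if (length(uniq) == 1L) return("identical")
  in_group <- function(gset) any(vapply(gset, function(g)
    all(uniq %in% strsplit(g, "")[[1]]), logical(1)))
  if (in_group(groups$strong)) return("conservative")
  if (in_group(groups$weak)) return("semi_conservative")
  "non_conserved"
}

#' Extrapolate catalogued mutations to homologous positions in other species
#'
#' Maps each record's mutated residue through the profile alignment into the
#' target species, reporting the homologous position (precursor numbering),
#' the target wild-type residue and the column conservation class. Catalogue
#' positions are precursor-numbered while alignment rows are mature
#' sequences, so signal-peptide lengths are subtracted and re-added
#' internally. Records falling inside the signal peptide or mapping onto a
#' target gap are emitted with NA position and flagged in `note`.
#'
#' @param records A catalogue data.frame.
#' @param aln A [profile_alignment()] whose rows are mature sequences keyed
#'   by species.
#' @param target_species Species to extrapolate into.
#' @param species_tab Species metadata table (signal lengths).
#' @return A data.frame with one row per record: `origin_id`,
#'   `target_species`, `target_pos`, `target_ref`, `conserved`, `note`.
#' @export
extrapolate_mutations <- function(records, aln, target_species,
                                  species_tab = species_table()) {
  validate_catalogue(records)
  stopifnot(inherits(aln, "profile_alignment"))
  if (nrow(records) == 0L)
    return(data.frame(origin_id = character(), target_species = character(),
                      target_pos = integer(), target_ref = character(),
                      conserved = character(), note = character(),
                      stringsAsFactors = FALSE))
  sig_to <- signal_length(target_species, species_tab)
  out <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    sig_from <- signal_length(rec$species, species_tab)
    mature <- rec$protein_pos - sig_from
    if (mature < 1L)
      return(data.frame(origin_id = rec$id, target_species = target_species,
                        target_pos = NA_integer_, target_ref = NA_character_,
                        conserved = NA_character_,
                        note = "within signal peptide",
                        stringsAsFactors = FALSE))
    mp <- map_position(aln, rec$species, mature, target_species)
    col <- attr(mp, "column")
    cons <- column_conservation(aln, col)
    if (is.na(mp))
      return(data.frame(origin_id = rec$id, target_species = target_species,
                        target_pos = NA_integer_, target_ref = NA_character_,
                        conserved = cons, note = "target gapped at column",
                        stringsAsFactors = FALSE))
    data.frame(origin_id = rec$id, target_species = target_species,
               target_pos = as.integer(mp) + sig_to,
               target_ref = aln_row(aln, target_species)[col],
               conserved = cons, note = "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Tabulate a full cross-species position map
#'
#' @param aln A [profile_alignment()].
#' @param from_species,to_species Row labels.
#' @return Data.frame `source_pos` / `target_pos` (NA where the target is
#'   gapped), positions on the ungapped rows.
#' @export
position_map <- function(aln, from_species, to_species) {
  n <- ungapped_length(aln, from_species)
  tp <- vapply(seq_len(n), function(p)
    as.integer(map_position(aln, from_species, p, to_species)), integer(1))
  data.frame(source_pos = seq_len(n), target_pos = tp,
             stringsAsFactors = FALSE)
}

#' Write an extrapolation or position-map table as TSV
#' @param x A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mapping_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}
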