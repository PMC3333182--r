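STOP_CODONS <- c("TAA", "TAG", "TGA")

check_nt_string <- function(seq, what = "sequence") {
  seq <- toupper(as_scalar_chr(seq))
  bad <- regexpr("[^ACGT]", seq)
  abort_if(bad > 0L,
           sprintf("non-ACGT character '%s' at position %d in %s",
                   substr(seq, bad, bad), bad, what))
  seq
}

#' Transcript model for a coding sequence
#'
#' Couples a validated coding sequence (CDS) with its species, signal-peptide
#' length and the integer offset that converts catalogue nucleotide
#' coordinates to CDS coordinates (`catalogue coordinate - CDS coordinate`;
#' default 0). The CDS must start with ATG, end with a stop codon, have
#' length divisible by 3 and contain no internal stop. The wild-type protein
#' is translated once and stored.
#'
#' @param species Species label. For the four study species the
#'   signal-peptide length defaults from [species_table()]; other labels
#'   (e.g. synthetic transcripts) must set `signal_peptide_len` explicitly.
#' @param cds Coding nucleotide sequence over A/C/G/T.
#' @param signal_peptide_len Signal-peptide length in residues.
#' @param coord_offset Catalogue-coordinate minus CDS-coordinate.
#' @return An object of class `transcript_model`.
#' @export
#' @examples
#' tr <- transcript_model("human", "ATGTGGGAAAAGTAA")
#' tr$protein
transcript_model <- function(species, cds, signal_peptide_len = NULL,
                             coord_offset = 0L) {
  cds <- check_nt_string(cds, "cds")
  abort_if(nchar(cds) %% 3L != 0L, "cds length must be divisible by 3")
  abort_if(substr(cds, 1L, 3L) != "ATG", "cds must begin with ATG")
  last <- substr(cds, nchar(cds) - 2L, nchar(cds))
  abort_if(!last %in% STOP_CODONS, "cds must end with a stop codon")
  protein <- translate_cds(cds)
  abort_if(!attr(protein, "stop_reached") ||
             nchar(protein) != nchar(cds) / 3L - 1L,
           "cds contains an internal stop codon")
  if (is.null(signal_peptide_len)) {
    abort_if(!species %in% MANBA_SPECIES,
             "signal_peptide_len must be given for species '", species, "'")
    signal_peptide_len <- signal_length(species)
  }
  signal_peptide_len <- as_scalar_int(signal_peptide_len, "signal_peptide_len")
  abort_if(signal_peptide_len < 0L || signal_peptide_len >= nchar(protein),
           "signal_peptide_len must be >= 0 and < protein length")
  structure(list(species = species, cds = cds,
                 signal_peptide_len = signal_peptide_len,
                 coord_offset = as_scalar_int(coord_offset, "coord_offset"),
                 protein = as.character(protein)),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("Transcript model (", x$species, "): CDS ", nchar(x$cds), " nt, protein ",
      nchar(x$protein), " aa, signal peptide ", x$signal_peptide_len,
      " aa, coord offset ", x$coord_offset, "\n", sep = "")
  invisible(x)
}

#' Describe a nucleotide-level edit
#'
#' @param kind "substitution", "insertion" or "deletion".
#' @param nt_start 1-based CDS position: the substituted base, the base after
#'   which insertion occurs, or the first deleted base.
#' @param nt_end Last affected base (substitution/deletion); defaults to
#'   `nt_start`.
#' @param bases Replacement bases (substitution), inserted bases (insertion),
#'   or the expected reference bases (deletion; checked when given).
#' @return An object of class `edit_event`.
#' @export
edit_event <- function(kind = c("substitution", "insertion", "deletion"),
                       nt_start, nt_end = NULL, bases = NULL) {
  kind <- match.arg(kind)
  nt_start <- as_scalar_int(nt_start, "nt_start")
  nt_end <- if (is.null(nt_end)) nt_start else as_scalar_int(nt_end, "nt_end")
  abort_if(nt_start < 1L, "nt_start must be >= 1")
  abort_if(nt_end < nt_start, "nt_end must be >= nt_start")
  if (!is.null(bases)) bases <- check_nt_string(bases, "edit bases")
  abort_if(kind == "insertion" && is.null(bases),
           "insertion requires the inserted bases")
  abort_if(kind == "substitution" && is.null(bases),
           "substitution requires replacement bases")
  structure(list(kind = kind, nt_start = nt_start, nt_end = nt_end,
                 bases = bases),
            class = "edit_event")
}

#' Apply a nucleotide edit to a coding sequence
#'
#' Substitution replaces the bases at `[nt_start, nt_end]`; insertion inserts
#' the given bases immediately after `nt_start`; deletion removes
#' `[nt_start, nt_end]` (verifying the deleted bases against the reference
#' when they are supplied). Downstream bases shift accordingly.
#'
#' @param cds Nucleotide string.
#' @param event An [edit_event()].
#' @return The edited nucleotide string.
#' @export
#' @examples
#' apply_edit("ATGAAATAA", edit_event("insertion", 3, bases = "C"))
#' apply_edit("ATGAAATAA", edit_event("deletion", 4, 6))
apply_edit <- function(cds, event) {
  stopifnot(inherits(event, "edit_event"))
  cds <- check_nt_string(cds, "cds")
  n <- nchar(cds)
  abort_if(event$nt_start > n || event$nt_end > n,
           sprintf("edit position %d-%d out of bounds for a %d nt sequence",
                   event$nt_start, event$nt_end, n))
  switch(event$kind,
    substitution = {
      abort_if(nchar(event$bases) != event$nt_end - event$nt_start + 1L,
               "substitution bases must match the replaced interval length")
      paste0(substr(cds, 1L, event$nt_start - 1L), event$bases,
             substr(cds, event$nt_end + 1L, n))
    },
    insertion = {
      paste0(substr(cds, 1L, event$nt_start), event$bases,
             substr(cds, event$nt_start + 1L, n))
    },
    deletion = {
      ref <- substr(cds, event$nt_start, event$nt_end)
      if (!is.null(event$bases))
        abort_if(ref != event$bases,
                 sprintf("deleted bases '%s' do not match reference '%s' at %d-%d",
                         event$bases, ref, event$nt_start, event$nt_end))
      paste0(substr(cds, 1L, event$nt_start - 1L),
             substr(cds, event$nt_end + 1L, n))
    })
}

#' Select the open reading frame starting at the first ATG
#'
#' Scans the sequence 5' to 3' across all offsets for the first ATG and
#' returns the subsequence from that ATG through the first in-frame stop
#' codon (inclusive) or the sequence end. The frame with methionine as the
#' first residue is thereby selected.
#'
#' @param seq Nucleotide string.
#' @return The ORF string with attribute `stop_reached` (logical) and
#'   `start_at` (1-based offset of the ATG).
#' @export
#' @examples
#' select_reading_frame("CCATGTGGTAA")
select_reading_frame <- function(seq) {
  seq <- check_nt_string(seq, "sequence")
  abort_if(nchar(seq) == 0L, "empty sequence")
  start <- regexpr("ATG", seq, fixed = TRUE)
  abort_if(start < 0L, "no start codon (ATG) found")
  tail <- substr(seq, start, nchar(seq))
  n_codon <- nchar(tail) %/% 3L
  stop_at <- NA_integer_
  for (k in seq_len(n_codon)) {
    codon <- substr(tail, 3L * k - 2L, 3L * k)
    if (codon %in% STOP_CODONS) { stop_at <- k; break }
  }
  orf <- if (is.na(stop_at)) tail else substr(tail, 1L, 3L * stop_at)
  attr(orf, "stop_reached") <- !is.na(stop_at)
  attr(orf, "start_at") <- as.integer(start)
  orf
}

#' Translate a coding sequence with the standard genetic code
#'
#' Standard code (NCBI table 1, via `Biostrings::GENETIC_CODE`); translation
#' stops at the first stop codon, which is not included in the output. A
#' trailing incomplete codon is ignored.
#'
#' @param orf Nucleotide string beginning with ATG.
#' @return Amino-acid string with attribute `stop_reached`.
#' @export
#' @examples
#' translate_cds("ATGTGGTAA")
translate_cds <- function(orf) {
  orf <- check_nt_string(orf, "orf")
  abort_if(nchar(orf) < 3L, "orf must be at least one codon long")
  abort_if(substr(orf, 1L, 3L) != "ATG", "orf must start with ATG")
  code <- Biostrings::GENETIC_CODE
  n_codon <- nchar(orf) %/% 3L
  starts <- 3L * seq_len(n_codon) - 2L
  codons <- substring(orf, starts, starts + 2L)
  aas <- unname(code[codons])
  stop_idx <- which(aas == "*")
  stop_reached <- length(stop_idx) > 0L
  keep <- if (stop_reached) seq_len(stop_idx[1L] - 1L) else seq_len(n_codon)
  out <- paste(aas[keep], collapse = "")
  attr(out, "stop_reached") <- stop_reached
  out
}

#' Truncation bookkeeping
#'
#' For a chain terminating after `stop_after_residue` residues of a
#' `wt_len`-residue wild type, the number of removed residues and the
#' retained fraction.
#'
#' @param wt_len Wild-type protein length (precursor numbering).
#' @param stop_after_residue Last translated residue.
#' @return List with `removed_count` and `retained_fraction`.
#' @export
#' @examples
#' truncation_extent(879, 857)  # cow W858X: 22 residues missing
truncation_extent <- function(wt_len, stop_after_residue) {
  wt_len <- as_scalar_int(wt_len, "wt_len")
  stop_after_residue <- as_scalar_int(stop_after_residue, "stop_after_residue")
  abort_if(stop_after_residue > wt_len,
           "stop_after_residue exceeds wild-type length")
  abort_if(stop_after_residue < 0L, "stop_after_residue must be >= 0")
  list(removed_count = wt_len - stop_after_residue,
       retained_fraction = stop_after_residue / wt_len)
}

new_mutant_protein_result <- function(mutant_seq, wt_len, is_truncated,
                                      stop_after_residue, non_stop = FALSE,
                                      substituted_pos = NA_integer_,
                                      wt_seq = NA_character_) {
  removed <- retained <- NA_real_
  if (!is.na(wt_len) && !is.na(stop_after_residue)) {
    ## a non-stop read-through can run past the wild-type length; no residues
    ## are then "removed" even though the tail diverges
    ext <- truncation_extent(wt_len, min(stop_after_residue, wt_len))
    removed <- ext$removed_count
    retained <- ext$retained_fraction
  }
  structure(list(mutant_seq = mutant_seq, wt_len = wt_len, wt_seq = wt_seq,
                 is_truncated = is_truncated,
                 stop_after_residue = stop_after_residue,
                 removed_count = removed, retained_fraction = retained,
                 non_stop = non_stop, substituted_pos = substituted_pos,
                 active_site_retained = NULL, active_site_complete = NA),
            class = "mutant_protein_result")
}

#' @export
print.mutant_protein_result <- function(x, ...) {
  cat("Mutant protein:",
      if (isTRUE(x$is_truncated))
        sprintf("truncated after residue %d (%d of %d removed)",
                x$stop_after_residue, x$removed_count, x$wt_len)
      else "full length", "\n")
  if (!is.na(x$active_site_complete))
    cat("  active site complete:", x$active_site_complete, "\n")
  invisible(x)
}

#' Flag retention of active-site residues in a mutant chain
#'
#' Each active-site position is retained iff it lies at or before the
#' truncation point (or the chain is full length) and the residue itself is
#' unmutated. When both mutant and wild-type sequences are available the
#' residue identity is compared directly (so frameshifted tails do not count
#' as retained); otherwise the recorded substitution position is used.
#'
#' @param mutant A `mutant_protein_result`.
#' @param as_def An [active_site_definition()].
#' @return The `mutant_protein_result` with `active_site_retained` (named
#'   logical vector) and `active_site_complete` filled in.
#' @export
active_site_retained <- function(mutant, as_def) {
  stopifnot(inherits(mutant, "mutant_protein_result"),
            inherits(as_def, "active_site_definition"))
  pos <- active_site_positions(as_def)
  retained <- vapply(pos, function(p) {
    ## unknown truncation point: conservatively count everything as lost
    if (isTRUE(mutant$is_truncated) && is.na(mutant$stop_after_residue))
      return(FALSE)
    if (isTRUE(mutant$is_truncated) && !is.na(mutant$stop_after_residue) &&
        p > mutant$stop_after_residue) return(FALSE)
    if (!is.na(mutant$substituted_pos) && p == mutant$substituted_pos)
      return(FALSE)
    if (!is.na(mutant$mutant_seq) && !is.na(mutant$wt_seq) &&
        p <= nchar(mutant$mutant_seq) && p <= nchar(mutant$wt_seq)) {
      return(substr(mutant$mutant_seq, p, p) == substr(mutant$wt_seq, p, p))
    }
    TRUE
  }, logical(1))
  names(retained) <- as.character(pos)
  mutant$active_site_retained <- retained
  mutant$active_site_complete <- all(retained)
  mutant
}

codons_for <- function(aa) {
  code <- Biostrings::GENETIC_CODE
  if (aa == STOP_SYMBOL) STOP_CODONS else sort(names(code)[code == aa])
}

## rewrite the codon of `protein_pos` to encode `alt`, changing as few bases
## as possible (ties broken alphabetically for determinism)
mutate_codon <- function(cds, protein_pos, ref, alt) {
  start <- 3L * protein_pos - 2L
  abort_if(start + 2L > nchar(cds),
           sprintf("residue %d lies beyond the CDS", protein_pos))
  codon <- substr(cds, start, start + 2L)
  cur <- unname(Biostrings::GENETIC_CODE[codon])
  abort_if(!is.na(ref) && cur != ref,
           sprintf("reference mismatch at residue %d: CDS encodes %s, record says %s",
                   protein_pos, cur, ref))
  cand <- codons_for(alt)
  dist <- vapply(cand, function(cc)
    sum(strsplit(cc, "")[[1]] != strsplit(codon, "")[[1]]), integer(1))
  new_codon <- cand[order(dist, cand)][1L]
  apply_edit(cds, edit_event("substitution", start, start + 2L, new_codon))
}

#' Translate a mutant transcript and quantify the consequence
#'
#' Applies a catalogue record to a transcript's CDS and translates the
#' result. Nonsense and missense records rewrite the affected codon (with a
#' minimal-base-change codon for the new residue or stop); insertions and
#' deletions are applied at the nucleotide level (coordinates resolved via
#' the transcript's `coord_offset`), after which the reading frame with
#' methionine as the first residue is re-selected and translated. A
#' frameshifted read-through that reaches the sequence end without a stop is
#' flagged `non_stop` and treated as truncating at the last full codon.
#'
#' @param transcript A [transcript_model()].
#' @param record A one-row catalogue data.frame.
#' @param as_def Optional [active_site_definition()] for retention flags.
#' @return A `mutant_protein_result`.
#' @export
#' @examples
#' tr <- transcript_model("human", "ATGTGGGAAAAGTGGTAA")
#' rec <- mutation_record("ex", "human", "nonsense", protein = "W5X")
#' translate_mutant(tr, rec)
translate_mutant <- function(transcript, record, as_def = NULL) {
  stopifnot(inherits(transcript, "transcript_model"))
  validate_catalogue(record)
  abort_if(nrow(record) != 1L, "expected a single record")
  wt <- transcript$protein
  wt_len <- nchar(wt)
  kind <- record$event_kind

  if (kind %in% c("nonsense", "missense")) {
    cds2 <- mutate_codon(transcript$cds, record$protein_pos,
                         record$protein_ref, record$protein_alt)
    prot <- translate_cds(cds2)
    non_stop <- !attr(prot, "stop_reached")
    mseq <- as.character(prot)
    truncated <- nchar(mseq) < wt_len || non_stop
    res <- new_mutant_protein_result(
      mutant_seq = mseq, wt_len = wt_len, is_truncated = truncated,
      stop_after_residue = nchar(mseq), non_stop = non_stop,
      substituted_pos = if (kind == "missense") record$protein_pos else NA_integer_,
      wt_seq = wt)
  } else {
    abort_if(is.na(record$nt_start),
             "record has no nucleotide coordinates; cannot edit the CDS")
    shift <- transcript$coord_offset
    ev <- if (kind == "insertion") {
      abort_if(is.na(record$inserted_bases),
               "insertion record has no inserted bases")
      edit_event("insertion", record$nt_start - shift,
                 bases = record$inserted_bases)
    } else {
      nt_end <- if (is.na(record$nt_end)) record$nt_start else record$nt_end
      edit_event("deletion", record$nt_start - shift, nt_end - shift,
                 bases = if (is.na(record$deleted_bases)) NULL else record$deleted_bases)
    }
    cds2 <- apply_edit(transcript$cds, ev)
    orf <- select_reading_frame(cds2)
    prot <- translate_cds(as.character(orf))
    non_stop <- !attr(prot, "stop_reached")
    mseq <- as.character(prot)
    truncated <- nchar(mseq) < wt_len || non_stop
    res <- new_mutant_protein_result(
      mutant_seq = mseq, wt_len = wt_len, is_truncated = truncated,
      stop_after_residue = nchar(mseq), non_stop = non_stop, wt_seq = wt)
  }
  if (!is.null(as_def)) res <- active_site_retained(res, as_def)
  res
}

#' Build a truncation result from a protein-level record
#'
#' For catalogue records carried at the protein level only (no usable
#' nucleotide coordinates), a premature stop at `protein_pos` terminates the
#' chain after residue `protein_pos - 1`. The wild-type length may be NA
#' when unknown (extent fields are then NA but active-site flags are still
#' computed).
#'
#' @param record A one-row catalogue data.frame with a truncating consequence.
#' @param wt_len Wild-type precursor length, or NA.
#' @param as_def Optional [active_site_definition()].
#' @return A `mutant_protein_result`.
#' @export
#' @examples
#' rec <- manba_catalogue()[manba_catalogue()$id == "Bt_W858X", ]
#' truncation_from_record(rec, wt_len = 879)
truncation_from_record <- function(record, wt_len = NA, as_def = NULL) {
  validate_catalogue(record)
  abort_if(nrow(record) != 1L, "expected a single record")
  abort_if(classify_consequence(record) != "truncating",
           "record is not truncating")
  if (is.na(record$protein_pos))
    warning(sprintf("record '%s' has no protein position; truncation point unknown, active-site loss assumed",
                    record$id))
  stop_after <- record$protein_pos - 1L
  wt_len_int <- if (is.na(wt_len)) NA_integer_ else as_scalar_int(wt_len, "wt_len")
  res <- new_mutant_protein_result(
    mutant_seq = NA_character_, wt_len = wt_len_int, is_truncated = TRUE,
    stop_after_residue = stop_after)
  if (!is.null(as_def)) res <- active_site_retained(res, as_def)
  res
}
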