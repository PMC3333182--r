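#' Cluster mutation positions into hot-spot segments
#'
#' Gap-threshold clustering along the gene: the sorted nucleotide positions
#' are split between consecutive members whenever the gap exceeds
#' `gap_threshold` (a gap exactly equal to the threshold does not split).
#' Segment boundaries are the positions of the first and last member of each
#' group.
#'
#' @param positions Data.frame with columns `id` and `nt` (sorted ascending
#'   by `nt`), or a numeric vector of positions (ids generated).
#' @param gap_threshold Maximum within-segment gap, in nucleotides (>= 1).
#' @return A `hotspot_segments` data.frame: `segment`, `start_nt`, `end_nt`,
#'   `length_nt`, `n_members`, and list-column `member_ids`.
#' @export
#' @examples
#' cluster_mutations(c(10, 20, 200, 210), gap_threshold = 50)
cluster_mutations <- function(positions, gap_threshold = 150L) {
  if (is.numeric(positions))
    positions <- data.frame(id = paste0("m", seq_along(positions)),
                            nt = as.integer(positions),
                            stringsAsFactors = FALSE)
  abort_if(!is.data.frame(positions) ||
             !all(c("id", "nt") %in% names(positions)),
           "positions must be a data.frame with columns 'id' and 'nt'")
  abort_if(nrow(positions) == 0L, "positions must be non-empty")
  abort_if(any(is.na(positions$nt)), "positions must not contain NA")
  abort_if(is.unsorted(positions$nt),
           "positions must be sorted ascending by nt")
  gap_threshold <- as_scalar_int(gap_threshold, "gap_threshold")
  abort_if(gap_threshold < 1L, "gap_threshold must be >= 1")
  nt <- positions$nt
  breaks <- which(diff(nt) > gap_threshold)
  group <- cumsum(c(1L, as.integer(seq_along(nt)[-1] %in% (breaks + 1L))))
  segs <- lapply(unique(group), function(g) {
    sel <- group == g
    data.frame(segment = g, start_nt = min(nt[sel]), end_nt = max(nt[sel]),
               length_nt = max(nt[sel]) - min(nt[sel]) + 1L,
               n_members = sum(sel), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, segs)
  out$member_ids <- lapply(unique(group),
                           function(g) positions$id[group == g])
  class(out) <- c("hotspot_segments", "data.frame")
  out
}

#' Length of hot-spot segments in nucleotides
#'
#' `end_nt - start_nt + 1` per segment (both boundary mutations included).
#'
#' @param seg A `hotspot_segments` data.frame (or any data.frame with
#'   `start_nt` and `end_nt`).
#' @return Integer vector of segment lengths.
#' @export
#' @examples
#' segment_length(manba_hotspot_segments())
segment_length <- function(seg) {
  abort_if(!all(c("start_nt", "end_nt") %in% names(seg)),
           "segments need start_nt and end_nt columns")
  abort_if(any(seg$end_nt < seg$start_nt), "end_nt must be >= start_nt")
  as.integer(seg$end_nt - seg$start_nt + 1L)
}

#' Protein residues whose codons overlap a hot-spot segment
#'
#' Residue r occupies CDS nucleotides `[3r-2, 3r]`; with a catalogue
#' coordinate offset the codon interval is `[3r-2+offset, 3r+offset]`. Every
#' residue whose codon intersects `[start_nt, end_nt]` is reported --
#' partial codon overlap counts, since a boundary mutation affects that
#' codon.
#'
#' @param seg A one-row segment (or list with `start_nt`, `end_nt`).
#' @param coord_offset Catalogue-coordinate minus CDS-coordinate.
#' @return Integer vector of residue positions (precursor numbering of the
#'   CDS the offset refers to).
#' @export
#' @examples
#' residues_covered(list(start_nt = 1363, end_nt = 1541))
residues_covered <- function(seg, coord_offset = 0L) {
  start_nt <- as_scalar_int(seg$start_nt, "start_nt")
  end_nt <- as_scalar_int(seg$end_nt, "end_nt")
  coord_offset <- as_scalar_int(coord_offset, "coord_offset")
  abort_if(end_nt < start_nt, "end_nt must be >= start_nt")
  lo <- start_nt - coord_offset
  hi <- end_nt - coord_offset
  abort_if(lo < 1L, "offset produces CDS positions < 1")
  first <- ceiling(lo / 3)
  last <- ceiling(hi / 3)
  seq.int(first, last)
}

#' Write hot-spot segments as TSV or BED
#'
#' The TSV report keeps 1-based inclusive coordinates; the BED writer
#' converts to 0-based half-open intervals at the boundary (and only there).
#'
#' @param seg A `hotspot_segments` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hotspots_tsv <- function(seg, path) {
  out <- as.data.frame(seg)
  out$member_ids <- vapply(out$member_ids, paste, character(1), collapse = ",")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' @rdname write_hotspots_tsv
#' @param chrom Chromosome/sequence name for the BED records.
#' @export
write_hotspots_bed <- function(seg, path, chrom = "MANBA") {
  bed <- data.frame(chrom = chrom,
                    start = seg$start_nt - 1L,  # 0-based half-open
                    end = seg$end_nt,
                    name = paste0("hotspot_", seg$segment),
                    stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
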