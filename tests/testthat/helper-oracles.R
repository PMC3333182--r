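# Independent oracles and small builders shared across the test files.

# exhaustive all-atom-pair minimum distance, independent of the package's
# vectorized implementation
brute_force_min_distance <- function(s, i, j) {
  ai <- s$atoms[s$atoms$resno == i & !s$atoms$elesy %in% c("H", "D"), ]
  aj <- s$atoms[s$atoms$resno == j & !s$atoms$elesy %in% c("H", "D"), ]
  best <- Inf
  for (a in seq_len(nrow(ai))) {
    for (b in seq_len(nrow(aj))) {
      d <- sqrt((ai$x[a] - aj$x[b])^2 + (ai$y[a] - aj$y[b])^2 +
                  (ai$z[a] - aj$z[b])^2)
      if (d < best) best <- d
    }
  }
  best
}

# verify a segmentation against the gap-split rule by direct inspection
check_partition <- function(segments, positions, gap_threshold) {
  ids <- unlist(segments$member_ids)
  if (!setequal(ids, positions$id) || anyDuplicated(ids) > 0) return(FALSE)
  nt <- positions$nt[match(ids, positions$id)]
  # within-segment gaps <= threshold, boundaries = first/last member
  off <- 0
  for (k in seq_len(nrow(segments))) {
    m <- segments$n_members[k]
    seg_nt <- nt[(off + 1):(off + m)]
    if (any(diff(seg_nt) > gap_threshold)) return(FALSE)
    if (segments$start_nt[k] != min(seg_nt) ||
        segments$end_nt[k] != max(seg_nt)) return(FALSE)
    off <- off + m
  }
  # between adjacent segments the gap must exceed the threshold
  if (nrow(segments) > 1) {
    gaps <- segments$start_nt[-1] - segments$end_nt[-nrow(segments)]
    if (any(gaps <= gap_threshold)) return(FALSE)
  }
  TRUE
}

# locate an alignment column by scanning and counting non-gap characters
brute_force_map <- function(aln, from, pos, to) {
  src <- strsplit(aln$rows[[from]], "")[[1]]
  tgt <- strsplit(aln$rows[[to]], "")[[1]]
  seen <- 0
  for (col in seq_along(src)) {
    if (src[col] != "-") {
      seen <- seen + 1
      if (seen == pos) {
        if (tgt[col] == "-") return(NA_integer_)
        return(sum(tgt[seq_len(col)] != "-"))
      }
    }
  }
  NA_integer_
}

random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

transform_structure <- function(s, rot, shift) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(rot)
  s$atoms$x <- xyz[, 1] + shift[1]
  s$atoms$y <- xyz[, 2] + shift[2]
  s$atoms$z <- xyz[, 3] + shift[3]
  s
}

write_toy_clustal <- function(rows, path) {
  writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "", "",
               sprintf("%-10s %s", names(rows), rows),
               sprintf("%-10s %s", "", strrep(" ", nchar(rows[[1]]))), ""),
             path)
  path
}

# a single-atom-per-residue structure at given coordinates
point_structure <- function(coords, resno = seq_len(nrow(coords))) {
  structure_model(data.frame(
    resno = resno, resid = "ALA", elety = "CA", elesy = "C",
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    stringsAsFactors = FALSE))
}

# CDS of `len` residues, all alanine except a tryptophan planted at `trp_at`
trp_planted_cds <- function(len, trp_at) {
  codons <- rep("GCT", len)
  codons[1] <- "ATG"
  codons[trp_at] <- "TGG"
  paste0(paste(codons, collapse = ""), "TAA")
}
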