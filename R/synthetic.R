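with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification for the synthetic study system
#'
#' Deterministic, seeded generators produce a toy transcript/protein, a
#' mutation catalogue with planted 1-D cluster structure, and a 3-D
#' structure with a planted active-site pocket at known distances, so every
#' pipeline stage is testable without downloads.
#'
#' @param seed Integer seed; all generators are bit-reproducible from
#'   (seed, spec).
#' @param n_residues Protein length (>= signal_len + 10).
#' @param signal_len Signal-peptide length.
#' @param active_site_positions Residues forming the planted pocket (first
#'   two are taken as "catalytic", the rest as "binding").
#' @param planted_clusters Data.frame with columns `start_nt`, `end_nt`,
#'   `n_mutations`: non-overlapping, ascending CDS intervals, separated by
#'   more than `intra_cluster_gap`. The default plants two 3-mutation
#'   clusters spanning roughly the 10-30% and 60-80% stretches of the CDS;
#'   NULL plants nothing.
#' @param intra_cluster_gap Maximum spacing between consecutive planted
#'   mutations inside a cluster (also the recovery threshold).
#' @param pocket_radius_A Radius of the sphere holding the pocket residues.
#' @param decoy_distance_A Planted distance of the far probe residue.
#' @param probe_distances_A Planted probe distances (defaults to a near
#'   probe at 2 Angstrom and the decoy).
#' @return A list of class `synthetic_spec`.
#' @export
#' @examples
#' sp <- synthetic_spec(seed = 1)
#' tp <- generate_transcript(sp)
#' nchar(tp$transcript$cds)
synthetic_spec <- function(seed, n_residues = 100L, signal_len = 17L,
                           active_site_positions = c(40L, 41L, 60L),
                           planted_clusters = default_clusters(n_residues),
                           intra_cluster_gap = 30L,
                           pocket_radius_A = 4,
                           decoy_distance_A = 25,
                           probe_distances_A = c(2, decoy_distance_A)) {
  seed <- as_scalar_int(seed, "seed")
  n_residues <- as_scalar_int(n_residues, "n_residues")
  signal_len <- as_scalar_int(signal_len, "signal_len")
  abort_if(n_residues < signal_len + 10L,
           "n_residues must be at least signal_len + 10")
  active_site_positions <- sort(unique(as.integer(active_site_positions)))
  abort_if(any(active_site_positions < 2L) ||
             any(active_site_positions > n_residues),
           "active-site positions must lie within the protein")
  pc <- planted_clusters
  if (!is.null(pc) && nrow(pc) > 0L) {
    abort_if(!all(c("start_nt", "end_nt", "n_mutations") %in% names(pc)),
             "planted_clusters needs start_nt, end_nt, n_mutations")
    abort_if(is.unsorted(pc$start_nt, strictly = TRUE),
             "planted clusters must be sorted by start_nt")
    abort_if(any(pc$end_nt < pc$start_nt), "cluster end before start")
    abort_if(any(pc$start_nt < 4L) || any(pc$end_nt > 3L * n_residues),
             "clusters must lie within codons 2..n_residues of the CDS")
    if (nrow(pc) > 1L)
      abort_if(any(pc$start_nt[-1] - pc$end_nt[-nrow(pc)] <= intra_cluster_gap),
               "inter-cluster gaps must exceed intra_cluster_gap")
    abort_if(any(pc$end_nt - pc$start_nt < pc$n_mutations - 1L),
             "infeasible spacing: cluster too narrow for its mutation count")
  }
  structure(list(seed = seed, n_residues = n_residues,
                 signal_len = signal_len,
                 active_site_positions = active_site_positions,
                 planted_clusters = pc,
                 intra_cluster_gap = as_scalar_int(intra_cluster_gap,
                                                   "intra_cluster_gap"),
                 pocket_radius_A = pocket_radius_A,
                 decoy_distance_A = decoy_distance_A,
                 probe_distances_A = probe_distances_A),
            class = "synthetic_spec")
}

default_clusters <- function(n_residues) {
  L <- 3L * as.integer(n_residues)
  data.frame(start_nt = c(max(4L, round(0.1 * L)), round(0.6 * L)),
             end_nt = c(round(0.3 * L), round(0.8 * L)),
             n_mutations = c(3L, 3L))
}

SENSE_CODONS <- setdiff(
  apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                    c("T", "C", "A", "G"), stringsAsFactors = FALSE),
        1L, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

#' Generate a synthetic transcript and its protein
#'
#' A random CDS with a valid start (ATG), no internal stop, and a terminal
#' TAA; `translate_cds(cds)` reproduces the returned protein exactly.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `transcript` (a [transcript_model()], species
#'   "synthetic") and `protein` (amino-acid string).
#' @export
generate_transcript <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    body <- sample(SENSE_CODONS, spec$n_residues - 1L, replace = TRUE)
    cds <- paste0("ATG", paste(body, collapse = ""), "TAA")
    tr <- transcript_model("synthetic", cds,
                           signal_peptide_len = spec$signal_len)
    list(transcript = tr, protein = tr$protein)
  })
}

#' Plant a mutation catalogue with known cluster structure
#'
#' For each planted cluster the first mutation sits on the cluster start and
#' successive mutations follow at gaps drawn from 1..intra_cluster_gap
#' (clamped to fit the cluster span), so consecutive within-cluster gaps
#' never exceed the threshold while between-cluster gaps always do. Event
#' kinds cycle through nonsense, missense, frameshifting insertion and
#' frameshifting deletion. The true partition is attached as attribute
#' `clusters` (list of id vectors) for recovery testing.
#'
#' @param spec A [synthetic_spec()].
#' @param transcript The output of [generate_transcript()].
#' @return A catalogue data.frame with attribute `clusters`.
#' @export
plant_mutations <- function(spec, transcript) {
  stopifnot(inherits(spec, "synthetic_spec"))
  tr <- transcript$transcript %||% transcript
  stopifnot(inherits(tr, "transcript_model"))
  pc <- spec$planted_clusters
  if (is.null(pc) || nrow(pc) == 0L) {
    out <- manba_catalogue()[0, ]
    attr(out, "clusters") <- list()
    return(out)
  }
  protein <- tr$protein
  kinds <- c("nonsense", "missense", "insertion", "deletion")
  with_seed(spec$seed + 1L, {
    recs <- list(); truth <- list(); k <- 0L
    for (ci in seq_len(nrow(pc))) {
      n <- pc$n_mutations[ci]
      span <- pc$end_nt[ci] - pc$start_nt[ci]
      max_gap <- max(1L, min(spec$intra_cluster_gap,
                             if (n > 1L) span %/% (n - 1L) else span))
      gaps <- if (n > 1L) sample.int(max_gap, n - 1L, replace = TRUE) else integer()
      nts <- pc$start_nt[ci] + cumsum(c(0L, gaps))
      ids <- character(n)
      for (m in seq_len(n)) {
        k <- k + 1L
        id <- sprintf("SYN%03d", k)
        ids[m] <- id
        nt <- nts[m]
        kind <- kinds[(k - 1L) %% length(kinds) + 1L]
        res_pos <- ceiling(nt / 3)
        ref <- substr(protein, res_pos, res_pos)
        recs[[k]] <- switch(kind,
          nonsense = mutation_record(id, "human", "nonsense",
                                     nt_start = nt, nt_end = nt,
                                     protein_ref = ref, protein_pos = res_pos,
                                     protein_alt = STOP_SYMBOL,
                                     source_note = "synthetic"),
          missense = mutation_record(id, "human", "missense",
                                     nt_start = nt, nt_end = nt,
                                     protein_ref = ref, protein_pos = res_pos,
                                     protein_alt = sample(setdiff(AA_LETTERS, ref), 1L),
                                     source_note = "synthetic"),
          insertion = mutation_record(id, "human", "insertion",
                                      nt_start = nt,
                                      inserted_bases = paste(
                                        sample(c("A", "C", "G", "T"),
                                               sample(c(1L, 2L, 4L), 1L),
                                               replace = TRUE), collapse = ""),
                                      source_note = "synthetic"),
          deletion = mutation_record(id, "human", "deletion",
                                     nt_start = nt,
                                     nt_end = nt + sample(c(0L, 1L), 1L),
                                     deleted_bases = NA,
                                     source_note = "synthetic"))
        recs[[k]]$deleted_bases <- if (kind == "deletion")
          substr(tr$cds, recs[[k]]$nt_start, recs[[k]]$nt_end) else
            recs[[k]]$deleted_bases
      }
      truth[[ci]] <- ids
    }
    out <- do.call(rbind, recs)
    validate_catalogue(out)
    attr(out, "clusters") <- truth
    out
  })
}

aa_three <- function(aa) {
  three <- bio3d::aa123(aa)
  three[is.na(three) | three == ""] <- "GLY"
  three
}

#' Generate a synthetic 3-D structure with a planted active-site pocket
#'
#' One pseudo-atom per residue (an alpha-carbon-like center): the chain is
#' laid out on a self-avoiding 3-D random walk (3.8 Angstrom steps), the
#' active-site residues are relocated into a sphere of radius
#' `pocket_radius_A` around a remote pocket center, and designated probe
#' residues (the highest-numbered non-active-site residues, one per entry
#' of `probe_distances_A`) are placed at exactly those distances from the
#' pocket. The exact planted distances are attached as attribute
#' `ground_truth` (data.frame `resno`, `distance_A`, `nearest`).
#'
#' @param spec A [synthetic_spec()].
#' @param protein Amino-acid string (as from [generate_transcript()]).
#' @return A `structure_model` with attribute `ground_truth`.
#' @export
generate_structure <- function(spec, protein) {
  stopifnot(inherits(spec, "synthetic_spec"))
  protein <- toupper(as_scalar_chr(protein))
  n <- nchar(protein)
  as_pos <- spec$active_site_positions
  abort_if(any(as_pos > n), "active-site positions beyond protein length")
  with_seed(spec$seed + 2L, {
    ## self-avoiding walk
    coords <- matrix(NA_real_, n, 3L)
    coords[1L, ] <- c(0, 0, 0)
    for (i in seq_len(n)[-1L]) {
      placed <- FALSE
      for (try in seq_len(200L)) {
        u <- stats::rnorm(3L); u <- u / sqrt(sum(u^2))
        p <- coords[i - 1L, ] + 3.8 * u
        prev <- coords[seq_len(i - 1L), , drop = FALSE]
        if (min(sqrt(rowSums(sweep(prev, 2L, p)^2))) >= 3.0) {
          coords[i, ] <- p; placed <- TRUE; break
        }
      }
      abort_if(!placed, "self-avoiding walk placement failed")
    }
    ## planted pocket, far from the walk
    center <- c(150, 150, 150)
    for (p in as_pos) {
      u <- stats::rnorm(3L); u <- u / sqrt(sum(u^2))
      r <- spec$pocket_radius_A * stats::runif(1L)^(1 / 3)
      coords[p, ] <- center + r * u
    }
    ## probes at exact recorded distances from the pocket
    probes <- setdiff(seq_len(n), as_pos)
    probes <- utils::tail(probes, length(spec$probe_distances_A))
    gt <- list()
    pocket <- coords[as_pos, , drop = FALSE]
    for (k in seq_along(probes)) {
      d <- spec$probe_distances_A[k]
      placed <- FALSE
      for (try in seq_len(200L)) {
        u <- stats::rnorm(3L); u <- u / sqrt(sum(u^2))
        anchor <- which.max(pocket %*% u)
        p <- pocket[anchor, ] + d * u
        dists <- sqrt(rowSums(sweep(pocket, 2L, p)^2))
        if (abs(min(dists) - d) < 1e-9) {
          coords[probes[k], ] <- p
          gt[[k]] <- data.frame(resno = probes[k], distance_A = min(dists),
                                nearest = as_pos[which.min(dists)])
          placed <- TRUE; break
        }
      }
      abort_if(!placed, "probe placement failed")
    }
    atoms <- data.frame(
      resno = seq_len(n),
      resid = aa_three(strsplit(protein, "")[[1]]),
      elety = "CA", elesy = "C",
      x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
      stringsAsFactors = FALSE)
    s <- structure_model(atoms, chain = "A")
    attr(s, "ground_truth") <- do.call(rbind, gt)
    s
  })
}

#' Synthetic active-site definition matching a [synthetic_spec()]
#'
#' The first two planted pocket positions are treated as catalytic
#' nucleophiles and the remainder as binding residues.
#'
#' @param spec A [synthetic_spec()].
#' @return An [active_site_definition()].
#' @export
synthetic_active_site <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  pos <- spec$active_site_positions
  active_site_definition(catalytic = pos[seq_len(min(2L, length(pos)))],
                         binding = if (length(pos) > 2L) pos[-(1:2)] else integer())
}

#' Write a transcript/protein pair as FASTA
#'
#' @param transcript A [transcript_model()].
#' @param cds_path,protein_path Output paths (either may be NULL to skip).
#' @return Invisibly, a list of the written paths.
#' @export
write_transcript_fasta <- function(transcript, cds_path = NULL,
                                   protein_path = NULL) {
  stopifnot(inherits(transcript, "transcript_model"))
  if (!is.null(cds_path)) {
    x <- Biostrings::DNAStringSet(transcript$cds)
    names(x) <- paste0(transcript$species, "_cds")
    Biostrings::writeXStringSet(x, cds_path)
  }
  if (!is.null(protein_path)) {
    x <- Biostrings::AAStringSet(transcript$protein)
    names(x) <- paste0(transcript$species, "_protein")
    Biostrings::writeXStringSet(x, protein_path)
  }
  invisible(list(cds = cds_path, protein = protein_path))
}
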