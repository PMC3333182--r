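BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

## side-chain nitrogen atoms carrying a positive charge at lysosomal pH
BASIC_SIDECHAIN_N <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                          HIS = c("ND1", "NE2"))
## side-chain carboxylate oxygens
ACIDIC_SIDECHAIN_O <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

#' Read a protein structure from a PDB file
#'
#' ATOM records become the residue model; HETATM records are retained
#' separately as ligands (water is dropped -- the analysis never uses water
#' molecules). Parsing is delegated to `bio3d::read.pdb()`.
#'
#' @param path Path to a PDB-format coordinate file.
#' @param chain Optional chain identifier to restrict to.
#' @return An object of class `structure_model`: a list with `atoms` and
#'   `ligands` data.frames (columns `resno`, `resid`, `elety`, `elesy`,
#'   `x`, `y`, `z`) and `chain`.
#' @export
read_structure <- function(path, chain = NULL) {
  abort_if(!file.exists(path), "PDB file not found: ", path)
  abort_if(file.size(path) == 0L, "PDB file is empty: ", path)
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path)),
                  error = function(e) stop("failed to parse PDB '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  at <- pdb$atom
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  abort_if(nrow(at) == 0L, "no atoms found in ", path)
  cols <- c("resno", "resid", "elety", "elesy", "x", "y", "z")
  if (!"elesy" %in% names(at) || all(is.na(at$elesy)))
    at$elesy <- substr(gsub("[0-9]", "", at$elety), 1L, 1L)
  atoms <- at[at$type == "ATOM", cols, drop = FALSE]
  ligands <- at[at$type == "HETATM" & !at$resid %in% c("HOH", "WAT"),
                cols, drop = FALSE]
  rownames(atoms) <- rownames(ligands) <- NULL
  structure_model(atoms, ligands, chain = unique(at$chain)[1L])
}

#' @rdname read_structure
#' @param atoms,ligands Data.frames with columns `resno`, `resid`, `elety`,
#'   `elesy`, `x`, `y`, `z`.
#' @export
structure_model <- function(atoms, ligands = NULL, chain = "A") {
  need <- c("resno", "resid", "elety", "elesy", "x", "y", "z")
  abort_if(!all(need %in% names(atoms)),
           "atoms must have columns: ", paste(need, collapse = ", "))
  abort_if(!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)),
           "non-finite coordinates")
  if (is.null(ligands))
    ligands <- atoms[0, , drop = FALSE]
  structure(list(chain = chain, atoms = atoms, ligands = ligands),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("Structure model: chain", x$chain, "-",
      length(unique(x$atoms$resno)), "residues,", nrow(x$atoms), "atoms,",
      nrow(x$ligands), "ligand atoms\n")
  invisible(x)
}

residue_atoms <- function(s, resno, heavy_only = TRUE) {
  stopifnot(inherits(s, "structure_model"))
  at <- s$atoms[s$atoms$resno == resno, , drop = FALSE]
  if (heavy_only) at <- at[!at$elesy %in% c("H", "D"), , drop = FALSE]
  abort_if(nrow(at) == 0L,
           sprintf("residue %d not present in the structure (or has no heavy atoms)",
                   as.integer(resno)))
  at
}

xyz_matrix <- function(at) as.matrix(at[, c("x", "y", "z"), drop = FALSE])

min_pair_distance <- function(a, b) {
  ## minimum Euclidean distance between two coordinate sets
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

#' Minimum heavy-atom distance between two residues
#'
#' The minimum over all heavy-atom pairs of the Euclidean distance, in
#' Angstrom. Hydrogens are excluded (homology models and X-ray templates
#' lack them).
#'
#' @param s A `structure_model`.
#' @param i,j Residue numbers.
#' @return Distance in Angstrom.
#' @export
min_residue_distance <- function(s, i, j) {
  a <- xyz_matrix(residue_atoms(s, i))
  if (identical(as.integer(i), as.integer(j))) return(0)
  b <- xyz_matrix(residue_atoms(s, j))
  min_pair_distance(a, b)
}

#' Minimum distance from a residue to the enzyme active site
#'
#' Minimum of [min_residue_distance()] over all active-site members
#' (catalytic nucleophiles and binding residues) present in the model; ties
#' are broken towards the lower residue number.
#'
#' @param s A `structure_model`.
#' @param residue Residue number.
#' @param as_def An [active_site_definition()].
#' @return List with `distance_A` and `nearest` (the active-site residue
#'   realizing the minimum).
#' @export
distance_to_active_site <- function(s, residue, as_def) {
  stopifnot(inherits(as_def, "active_site_definition"))
  members <- active_site_positions(as_def)
  members <- members[members %in% unique(s$atoms$resno)]
  abort_if(length(members) == 0L,
           "no active-site residue present in the model")
  d <- vapply(members, function(m) min_residue_distance(s, residue, m),
              numeric(1))
  k <- which.min(d)  # members sorted ascending: ties go to the lower resno
  list(distance_A = d[k], nearest = members[k])
}

#' Classify proximity to the active site
#'
#' "close" iff the distance is at or below the threshold (boundary
#' inclusive), "away" otherwise. The default 8 Angstrom minimal heavy-atom
#' distance separates direct/first-shell contacts from remote positions.
#'
#' @param distance_A Distance in Angstrom (>= 0).
#' @param threshold_A Proximity threshold in Angstrom.
#' @return "close" or "away".
#' @export
#' @examples
#' proximity_class(2, 8)
#' proximity_class(25, 8)
proximity_class <- function(distance_A, threshold_A = 8) {
  abort_if(!is.finite(distance_A) || distance_A < 0,
           "distance must be a non-negative number")
  abort_if(threshold_A <= 0, "threshold must be positive")
  if (distance_A <= threshold_A) "close" else "away"
}

#' Record a lost inter-residue contact
#'
#' Helper used when feeding structural evidence to the severity classifier:
#' a contact (salt bridge, hydrogen bond, ...) present in the wild type and
#' broken by a substitution.
#'
#' @param type Contact type label.
#' @param partner_residue Residue number of the contact partner.
#' @param catalytic_adjacent Is the partner sequence-adjacent to a catalytic
#'   nucleophile (so breaking the contact disturbs the active site)?
#' @param fold_destabilizing Does losing the contact destabilize the overall
#'   fold?
#' @return A one-row data.frame.
#' @export
contact_lost <- function(type, partner_residue,
                         catalytic_adjacent = FALSE,
                         fold_destabilizing = FALSE) {
  data.frame(type = type, partner_residue = as.integer(partner_residue),
             catalytic_adjacent = isTRUE(catalytic_adjacent),
             fold_destabilizing = isTRUE(fold_destabilizing),
             stringsAsFactors = FALSE)
}

#' Detect simple geometric contacts between two residues
#'
#' Distance-only criteria on heavy atoms: a salt bridge is called when a
#' basic side-chain nitrogen (Arg NE/NH1/NH2, Lys NZ, His ND1/NE2) lies
#' within `salt_bridge_A` of an acidic side-chain oxygen (Asp OD1/OD2, Glu
#' OE1/OE2); a hydrogen-bond candidate when any side-chain N/O
#' donor-acceptor pair lies within `hbond_A`. No angular terms are applied.
#'
#' @param s A `structure_model`.
#' @param i,j Residue numbers.
#' @param salt_bridge_A,hbond_A Distance thresholds in Angstrom.
#' @return An object of class `contact_report`: list with `residues`,
#'   `min_distance_A` and `classes` (subset of "salt_bridge",
#'   "hbond_candidate", or "none").
#' @export
detect_contacts <- function(s, i, j, salt_bridge_A = 4.0, hbond_A = 3.5) {
  ai <- residue_atoms(s, i)
  aj <- residue_atoms(s, j)
  overall <- min_pair_distance(xyz_matrix(ai), xyz_matrix(aj))
  side <- function(at) at[!at$elety %in% BACKBONE_ATOMS, , drop = FALSE]
  si <- side(ai); sj <- side(aj)
  classes <- character()
  if (nrow(si) == 0L || nrow(sj) == 0L) {
    warning(sprintf("residue %d or %d has no side-chain atoms; contact classes unavailable",
                    as.integer(i), as.integer(j)))
  } else {
    pick <- function(at, table) {
      if (nrow(at) == 0L) return(at)
      keep <- vapply(seq_len(nrow(at)), function(k)
        at$elety[k] %in% (table[[at$resid[k]]] %||% character()), logical(1))
      at[keep, , drop = FALSE]
    }
    sb_pair_min <- function(a, b) {
      if (nrow(a) == 0L || nrow(b) == 0L) Inf
      else min_pair_distance(xyz_matrix(a), xyz_matrix(b))
    }
    sb <- min(sb_pair_min(pick(si, BASIC_SIDECHAIN_N), pick(sj, ACIDIC_SIDECHAIN_O)),
              sb_pair_min(pick(sj, BASIC_SIDECHAIN_N), pick(si, ACIDIC_SIDECHAIN_O)))
    if (sb <= salt_bridge_A) classes <- c(classes, "salt_bridge")
    don_acc <- function(at) at[at$elesy %in% c("N", "O"), , drop = FALSE]
    hb <- sb_pair_min(don_acc(si), don_acc(sj))
    if (hb <= hbond_A) classes <- c(classes, "hbond_candidate")
  }
  if (length(classes) == 0L) classes <- "none"
  structure(list(residues = c(as.integer(i), as.integer(j)),
                 min_distance_A = overall, classes = classes),
            class = "contact_report")
}

#' @export
print.contact_report <- function(x, ...) {
  cat(sprintf("Contact %d-%d: min heavy-atom distance %.2f A; classes: %s\n",
              x$residues[1], x$residues[2], x$min_distance_A,
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Write a structure model to a PDB file
#'
#' Emits standard ATOM records (via `bio3d::write.pdb()`) so synthetic
#' structures flow through the same reader as real coordinate files.
#'
#' @param s A `structure_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(s, path) {
  stopifnot(inherits(s, "structure_model"))
  at <- s$atoms
  xyz <- as.vector(t(xyz_matrix(at)))
  bio3d::write.pdb(file = path, xyz = xyz, resno = at$resno, resid = at$resid,
                   elety = at$elety, chain = rep(s$chain, nrow(at)))
  invisible(path)
}
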