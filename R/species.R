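#' Species metadata for lysosomal beta-mannosidase
#'
#' The four species with reported or modelled MANBA data. `signal_len` is the
#' length of the N-terminal signal peptide removed in the mature enzyme
#' (17 residues; 19 in mouse). `chitobiase` records whether the species
#' expresses the exoglycosidase chitobiase at levels that can partially
#' compensate for beta-mannosidase loss (human and rodents: yes; ruminants:
#' no) -- this drives the ruminant escalation rule of the severity classifier.
#' `precursor_len` is the precursor (signal peptide included) protein length
#' where it is needed by the truncation bookkeeping; positions are always
#' precursor-numbered unless stated otherwise.
#'
#' @return A data.frame with columns `species`, `signal_len`, `chitobiase`,
#'   `precursor_len`.
#' @export
#' @examples
#' species_table()
species_table <- function() {
  data.frame(
    species       = c("human", "cow", "goat", "mouse"),
    signal_len    = c(17L, 17L, 17L, 19L),
    chitobiase    = c(TRUE, FALSE, FALSE, TRUE),
    precursor_len = c(879L, 879L, NA_integer_, NA_integer_),
    stringsAsFactors = FALSE
  )
}

MANBA_SPECIES <- c("human", "cow", "goat", "mouse")

species_info <- function(species, tab = species_table()) {
  species <- as_scalar_chr(species)
  row <- tab[tab$species == species, , drop = FALSE]
  abort_if(nrow(row) == 0L, sprintf("unknown species '%s'", species))
  row
}

signal_length <- function(species, tab = species_table()) {
  species_info(species, tab)$signal_len
}

#' Active-site definition for beta-mannosidase
#'
#' The catalytic nucleophiles (E457 and E554, housed in the TIM barrel) and
#' the substrate-gripping binding-site residues (the W190/D191/W192 motif plus
#' W390 and W657, on loops adjacent to E457). Positions are human precursor
#' numbering by default; all seven residues are conserved across the four
#' species.
#'
#' @param catalytic Integer positions of the catalytic nucleophiles.
#' @param binding Integer positions of the substrate binding residues.
#' @param numbering Either "precursor" or "mature".
#' @return An object of class `active_site_definition`.
#' @export
#' @examples
#' as_def <- active_site_definition()
#' active_site_positions(as_def)
active_site_definition <- function(catalytic = c(457L, 554L),
                                   binding = c(190L, 191L, 192L, 390L, 657L),
                                   numbering = c("precursor", "mature")) {
  numbering <- match.arg(numbering)
  catalytic <- sort(unique(as.integer(catalytic)))
  binding <- sort(unique(as.integer(binding)))
  abort_if(any(catalytic < 1L) || any(binding < 1L),
           "active-site positions must be >= 1")
  abort_if(length(intersect(catalytic, binding)) > 0L,
           "catalytic and binding sets must be disjoint")
  structure(list(catalytic = catalytic, binding = binding,
                 numbering = numbering),
            class = "active_site_definition")
}

#' @rdname active_site_definition
#' @param as_def An `active_site_definition`.
#' @export
active_site_positions <- function(as_def) {
  stopifnot(inherits(as_def, "active_site_definition"))
  sort(c(as_def$catalytic, as_def$binding))
}

#' @export
print.active_site_definition <- function(x, ...) {
  cat("Active site (", x$numbering, " numbering)\n", sep = "")
  cat("  catalytic nucleophiles:", paste(x$catalytic, collapse = ", "), "\n")
  cat("  binding residues:      ", paste(x$binding, collapse = ", "), "\n")
  invisible(x)
}
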