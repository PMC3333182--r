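SEVERITY_LEVELS <- c("mild", "moderate", "severe")

severity_rank <- function(klass) match(klass, SEVERITY_LEVELS)
severity_from_rank <- function(r) SEVERITY_LEVELS[max(1L, min(3L, r))]

#' Default severity-rule configuration
#'
#' Thresholds and modifiers of the rule-based genotype-to-phenotype
#' classifier. `proximity_A` separates "close to active site" from "away"
#' (minimal heavy-atom distance); `direct_interaction_A` marks direct
#' active-site interaction; `last_domain_boundary` is the precursor residue
#' before which a truncation removes the fold-stabilizing C-terminal
#' domain(s) (anchored on the V720X case); `salt_bridge_A` / `hbond_A` feed
#' contact detection. The species table supplies signal lengths and the
#' chitobiase rescue flag.
#'
#' @param proximity_A,direct_interaction_A,salt_bridge_A,hbond_A Distance
#'   thresholds in Angstrom.
#' @param last_domain_boundary Precursor residue number.
#' @param gap_threshold_nt Hot-spot clustering gap threshold (nucleotides).
#' @return A list of class `severity_config`.
#' @export
severity_config <- function(proximity_A = 8, direct_interaction_A = 4.5,
                            salt_bridge_A = 4.0, hbond_A = 3.5,
                            last_domain_boundary = 720L,
                            gap_threshold_nt = 150L) {
  vals <- list(proximity_A = proximity_A,
               direct_interaction_A = direct_interaction_A,
               salt_bridge_A = salt_bridge_A, hbond_A = hbond_A,
               last_domain_boundary = as.integer(last_domain_boundary),
               gap_threshold_nt = as.integer(gap_threshold_nt))
  abort_if(any(vapply(vals, function(v) !is.finite(v) || v <= 0, logical(1))),
           "all severity thresholds must be positive")
  structure(vals, class = "severity_config")
}

#' Read / write the severity configuration as YAML
#' @param path File path.
#' @param config A [severity_config()].
#' @return `read_severity_config` returns a `severity_config`;
#'   `write_severity_config` returns `path` invisibly.
#' @export
write_severity_config <- function(config, path) {
  stopifnot(inherits(config, "severity_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_severity_config
#' @export
read_severity_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(severity_config, vals)
}

new_severity_call <- function(klass, rationale, evidence = list()) {
  abort_if(!klass %in% SEVERITY_LEVELS, "invalid severity class")
  abort_if(length(rationale) == 0L, "rationale must be non-empty")
  structure(list(klass = klass, rationale = rationale, evidence = evidence),
            class = "severity_call")
}

#' @export
print.severity_call <- function(x, ...) {
  cat("Severity:", x$klass, "[", paste(x$rationale, collapse = ", "), "]\n")
  invisible(x)
}

## Zygosity handling shared by both classifiers. A recessive genotype is
## scored from its alleles: with a functional (or unrecorded) partner allele
## the genotype is rescued to mild; with a second catalogued pathogenic
## allele the genotype is scored from the more severe allele and attenuated
## by exactly one level (floor mild).
apply_zygosity <- function(base_klass, zygosity, partner_klass = NULL) {
  if (!zygosity %in% c("heterozygous", "compound_heterozygous"))
    return(list(klass = base_klass, attenuated = FALSE))
  if (is.null(partner_klass) || identical(partner_klass, "functional"))
    return(list(klass = "mild", attenuated = TRUE))
  eff <- severity_from_rank(max(severity_rank(base_klass),
                                severity_rank(partner_klass)) - 1L)
  list(klass = eff, attenuated = TRUE)
}

#' Classify the phenotype severity of a truncating mutation
#'
#' Structural base class: severe when any active-site residue is lost or
#' when the chain stops before the last-domain boundary (loss of the
#' C-terminal stabilizing domains); moderate when only a small C-terminal
#' tail is removed. Zygosity then attenuates recessive genotypes (see
#' Details), and in ruminants -- which lack the compensating exoglycosidase
#' chitobiase -- any truncation escalates to severe.
#'
#' @details For heterozygous or compound-heterozygous genotypes the call is
#' made on the genotype, not the lone allele: when the partner allele is
#' functional or unrecorded the genotype is rescued to mild; when the
#' partner is itself a catalogued pathogenic allele (pass its base class via
#' `partner_klass`) the genotype scores the more severe allele attenuated by
#' one level.
#'
#' @param record A one-row catalogue data.frame.
#' @param mutant A `mutant_protein_result` with active-site flags.
#' @param species Species label (defaults to the record's species).
#' @param config A [severity_config()].
#' @param partner_klass NULL / "functional", or the structural base class of
#'   the partner allele.
#' @return A `severity_call`.
#' @export
#' @examples
#' fx <- study_fixtures()
#' rec <- fx$catalogue[fx$catalogue$id == "Cp_W466X", ]
#' mut <- truncation_from_record(rec, wt_len = 879, as_def = fx$active_site)
#' classify_truncation(rec, mut)
classify_truncation <- function(record, mutant, species = record$species,
                                config = severity_config(),
                                partner_klass = NULL) {
  stopifnot(inherits(mutant, "mutant_protein_result"))
  abort_if(!isTRUE(mutant$is_truncated),
           "classify_truncation requires a truncated mutant")
  abort_if(is.null(mutant$active_site_retained),
           "mutant must carry active-site retention flags (see active_site_retained)")
  codes <- character()
  lost <- names(mutant$active_site_retained)[!mutant$active_site_retained]
  if (length(lost) > 0L) {
    codes <- c(codes, "TRUNC_LOSES_ACTIVE_SITE")
    base <- "severe"
  } else if (mutant$stop_after_residue < config$last_domain_boundary) {
    codes <- c(codes, "TRUNC_LAST_DOMAIN_LOSS")
    base <- "severe"
  } else {
    codes <- c(codes, "TRUNC_SMALL_TAIL")
    base <- "moderate"
  }
  zy <- apply_zygosity(base, record$zygosity, partner_klass)
  klass <- zy$klass
  if (zy$attenuated) codes <- c(codes, "HET_ATTENUATED")
  if (!species_info(species)$chitobiase && klass != "severe") {
    klass <- "severe"
    codes <- c(codes, "RUMINANT_NO_CHITOBIASE")
  } else if (!species_info(species)$chitobiase) {
    codes <- c(codes, "RUMINANT_NO_CHITOBIASE")
  }
  new_severity_call(klass, codes,
                    evidence = list(
                      stop_after_residue = mutant$stop_after_residue,
                      retained_fraction = mutant$retained_fraction,
                      lost_site_residues = as.integer(lost)))
}

#' Classify the phenotype severity of a substitution mutation
#'
#' Structural base class: severe for a direct active-site interaction
#' (distance at or below `direct_interaction_A`, an explicit
#' `direct_interaction` flag, or a lost contact whose partner is
#' sequence-adjacent to a catalytic nucleophile); moderate when close to the
#' active site (within `proximity_A`); moderate when away from the active
#' site but losing a fold-stabilizing contact; mild otherwise (minor
#' perturbation). Zygosity attenuation as for truncations.
#'
#' @param record A one-row missense catalogue record.
#' @param distance_A Minimal heavy-atom distance to the active site
#'   (NA when no structural model is available).
#' @param contacts_lost Data.frame of lost contacts (see [contact_lost()]),
#'   or NULL.
#' @param species Species label.
#' @param config A [severity_config()].
#' @param partner_klass As in [classify_truncation()].
#' @param close_to_as,direct_interaction,fold_destabilizing Optional logical
#'   overrides for the categorical evidence flags (used when only the
#'   categorical structural call is known).
#' @return A `severity_call`.
#' @export
#' @examples
#' rec <- manba_catalogue()[manba_catalogue()$id == "Hs_R641H", ]
#' classify_substitution(rec, close_to_as = FALSE,
#'                       contacts_lost = contact_lost("salt_bridge", 709,
#'                                                    fold_destabilizing = TRUE))
classify_substitution <- function(record, distance_A = NA_real_,
                                  contacts_lost = NULL,
                                  species = record$species,
                                  config = severity_config(),
                                  partner_klass = NULL,
                                  close_to_as = NULL,
                                  direct_interaction = NULL,
                                  fold_destabilizing = NULL) {
  validate_catalogue(record)
  abort_if(classify_consequence(record) != "substitution",
           "classify_substitution requires a substitution record")
  has_contacts <- !is.null(contacts_lost) && nrow(contacts_lost) > 0L
  direct <- isTRUE(direct_interaction) ||
    (is.finite(distance_A) && distance_A <= config$direct_interaction_A) ||
    (has_contacts && any(contacts_lost$catalytic_adjacent))
  close <- isTRUE(close_to_as) ||
    (is.finite(distance_A) && distance_A <= config$proximity_A)
  destab <- isTRUE(fold_destabilizing) ||
    (has_contacts && any(contacts_lost$fold_destabilizing))
  if (direct) {
    base <- "severe"; codes <- "SUBST_DIRECT_AS_INTERACTION"
  } else if (close) {
    base <- "moderate"; codes <- "SUBST_NEAR_AS"
  } else if (destab) {
    base <- "moderate"; codes <- "SUBST_FOLD_DESTABILIZING"
  } else {
    base <- "mild"; codes <- "SUBST_MINOR"
  }
  zy <- apply_zygosity(base, record$zygosity, partner_klass)
  if (zy$attenuated) codes <- c(codes, "HET_ATTENUATED")
  new_severity_call(zy$klass, codes,
                    evidence = list(distance_A = distance_A,
                                    close_to_as = close, direct = direct,
                                    fold_destabilizing = destab))
}

## structural base class only (no zygosity/species modifiers); used when a
## record serves as the partner allele of a biallelic genotype
base_severity <- function(record, mutants, evidence, as_def, config,
                          species_tab) {
  id <- record$id
  if (classify_consequence(record) == "truncating") {
    mut <- mutants[[id]] %||% truncation_from_record(
      record, wt_len = species_info(record$species, species_tab)$precursor_len,
      as_def = as_def)
    lost <- any(!mut$active_site_retained)
    if (lost || mut$stop_after_residue < config$last_domain_boundary)
      "severe" else "moderate"
  } else {
    ev <- evidence[[id]] %||% list()
    call <- do.call(classify_substitution,
                    c(list(record = record,
                           species = record$species, config = config),
                      ev[intersect(names(ev),
                                   c("distance_A", "contacts_lost", "close_to_as",
                                     "direct_interaction", "fold_destabilizing"))]))
    ## strip zygosity by re-deriving the base from the rationale
    code <- call$rationale[1]
    switch(code,
           SUBST_DIRECT_AS_INTERACTION = "severe",
           SUBST_NEAR_AS = "moderate",
           SUBST_FOLD_DESTABILIZING = "moderate",
           "mild")
  }
}

#' Classify every record of a mutation catalogue
#'
#' Runs the truncation or substitution classifier on each record. Truncating
#' records use supplied `mutant_protein_result` objects when given (keyed by
#' record id), otherwise a protein-level truncation is derived from the
#' record. Substitutions use the structural evidence list (keyed by id);
#' records without evidence are classified from sequence-only rules (the
#' substituted position relative to the active site) with a warning.
#' Biallelic genotypes listed in `partners` are scored from their more
#' severe allele before zygosity attenuation.
#'
#' @param records A catalogue data.frame.
#' @param mutants Named list of `mutant_protein_result` objects (optional).
#' @param evidence Named list of substitution evidence lists (optional);
#'   each may carry `distance_A`, `contacts_lost`, `close_to_as`,
#'   `direct_interaction`, `fold_destabilizing`.
#' @param as_def An [active_site_definition()].
#' @param config A [severity_config()].
#' @param partners Data.frame with columns `id`, `partner_id` (optional).
#' @param species_tab Species metadata table.
#' @return A data.frame with one row per record: id, species, consequence,
#'   severity class, rationale codes (';'-separated) and the observed
#'   phenotype for comparison.
#' @export
#' @examples
#' fx <- study_fixtures()
#' calls <- classify_all(fx$catalogue, evidence = fx$substitution_evidence,
#'                       partners = fx$partner_pairs)
#' table(calls$klass)
classify_all <- function(records, mutants = NULL, evidence = NULL,
                         as_def = active_site_definition(),
                         config = severity_config(), partners = NULL,
                         species_tab = species_table()) {
  validate_catalogue(records)
  if (nrow(records) == 0L)
    return(data.frame(id = character(), species = character(),
                      consequence = character(), klass = character(),
                      rationale = character(), observed = character(),
                      stringsAsFactors = FALSE))
  mutants <- mutants %||% list()
  evidence <- evidence %||% list()
  cons <- classify_consequence(records)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    partner_klass <- NULL
    if (!is.null(partners) && rec$id %in% partners$id) {
      pid <- partners$partner_id[partners$id == rec$id][1L]
      prec <- records[records$id == pid, , drop = FALSE]
      if (nrow(prec) == 1L)
        partner_klass <- base_severity(prec, mutants, evidence, as_def,
                                       config, species_tab)
    }
    if (cons[i] == "truncating") {
      mut <- mutants[[rec$id]] %||% truncation_from_record(
        rec, wt_len = species_info(rec$species, species_tab)$precursor_len,
        as_def = as_def)
      if (is.null(mut$active_site_retained))
        mut <- active_site_retained(mut, as_def)
      call <- classify_truncation(rec, mut, species = rec$species,
                                  config = config,
                                  partner_klass = partner_klass)
    } else {
      ev <- evidence[[rec$id]]
      if (is.null(ev)) {
        warning(sprintf("no structural evidence for substitution record '%s'; using sequence-only rules",
                        rec$id))
        pos <- rec$protein_pos
        ev <- list(
          direct_interaction = pos %in% active_site_positions(as_def) ||
            any(abs(pos - as_def$catalytic) <= 1L),
          close_to_as = FALSE, fold_destabilizing = FALSE)
      }
      call <- do.call(classify_substitution,
                      c(list(record = rec, species = rec$species,
                             config = config, partner_klass = partner_klass),
                        ev[intersect(names(ev),
                                     c("distance_A", "contacts_lost",
                                       "close_to_as", "direct_interaction",
                                       "fold_destabilizing"))]))
    }
    data.frame(id = rec$id, species = rec$species, consequence = cons[i],
               klass = call$klass,
               rationale = paste(call$rationale, collapse = ";"),
               observed = rec$observed_phenotype,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
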