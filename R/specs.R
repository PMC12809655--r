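#' Isotopologue definitions for the sulfamethoxazole fragments
#'
#' Returns the isotopologue specification table for one or more of the three
#' diagnostic SMX fragments: F99 (the isoxazole moiety, positive mode), F92
#' (the aniline ring, negative mode) and F64 (the SO2 group, negative mode).
#' Each row defines one isotopic species of a fragment: its explicit isotopic
#' formula, ionization polarity, whether it is the basepeak (the species
#' containing only the most abundant isotopes, the denominator of every
#' isotopologue ratio), and the m/z used for peak extraction.
#'
#' @param fragments Character vector of fragment labels to return; any of
#'   `"F99"`, `"F92"`, `"F64"`.
#' @return A tibble with columns `fragment_id`, `isotopologue`,
#'   `isotopic_formula`, `polarity`, `is_basepeak`, `mz`.
#' @examples
#' smx_isotopologues("F99")
#' @export
smx_isotopologues <- function(fragments = c("F99", "F92", "F64")) {
  all <- tibble::tribble(
    ~fragment_id, ~isotopologue, ~isotopic_formula, ~polarity, ~is_basepeak, ~mz,
    "F99", "M0",  "12C4 1H7 14N2 16O",      "positive", TRUE,  99.0553,
    "F99", "15N", "12C4 1H7 14N1 15N1 16O", "positive", FALSE, 100.0524,
    "F99", "13C", "13C1 12C3 1H7 14N2 16O", "positive", FALSE, 100.0587,
    "F92", "M0",  "12C6 1H6 14N1",          "negative", TRUE,  92.0507,
    "F92", "15N", "12C6 1H6 15N1",          "negative", FALSE, 93.0477,
    "F92", "13C", "13C1 12C5 1H6 14N1",     "negative", FALSE, 93.0541,
    "F64", "M0",  "32S1 16O2",              "negative", TRUE,  63.9623,
    "F64", "34S", "34S1 16O2",              "negative", FALSE, 65.9581,
    "F64", "33S", "33S1 16O2",              "negative", FALSE, 64.9617
  )
  unknown <- setdiff(fragments, unique(all$fragment_id))
  if (length(unknown) > 0) {
    abort(paste0("Unknown fragment(s): ", paste(unknown, collapse = ", ")))
  }
  dplyr::filter(all, .data$fragment_id %in% fragments)
}

#' Validate an isotopologue specification table
#'
#' Checks the structural invariants of a spec table: exactly one basepeak
#' per fragment, a single polarity per fragment, positive m/z, and
#' well-formed isotopic formulas with all atom counts at least 1.
#'
#' @param specs A data frame as returned by [smx_isotopologues()].
#' @return `specs` invisibly; errors describe the first violated invariant.
#' @export
validate_specs <- function(specs) {
  required <- c("fragment_id", "isotopologue", "isotopic_formula",
                "polarity", "is_basepeak", "mz")
  missing <- setdiff(required, names(specs))
  if (length(missing) > 0) {
    abort(paste0("Spec table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(!specs$polarity %in% c("positive", "negative"))) {
    abort("`polarity` must be 'positive' or 'negative'.")
  }
  if (any(!is.finite(specs$mz) | specs$mz <= 0)) {
    abort("All `mz` values must be positive.")
  }
  by_frag <- dplyr::summarise(
    dplyr::group_by(specs, .data$fragment_id),
    n_base = sum(.data$is_basepeak),
    n_pol = dplyr::n_distinct(.data$polarity),
    .groups = "drop"
  )
  bad_base <- by_frag$fragment_id[by_frag$n_base != 1L]
  if (length(bad_base) > 0) {
    abort(paste0("Fragment(s) without exactly one basepeak: ",
                 paste(bad_base, collapse = ", ")))
  }
  bad_pol <- by_frag$fragment_id[by_frag$n_pol != 1L]
  if (length(bad_pol) > 0) {
    abort(paste0("Fragment(s) with mixed polarity: ",
                 paste(bad_pol, collapse = ", ")))
  }
  for (f in specs$isotopic_formula) {
    atoms <- parse_isotopic_formula(f)
    if (any(atoms$count < 1)) {
      abort(paste0("Formula with atom count < 1: ", f))
    }
  }
  invisible(specs)
}

#' Element measured by a rare isotopologue
#'
#' Maps isotopologue labels (`"13C"`, `"15N"`, `"34S"`, `"33S"`) to the
#' element ratio they report; the basepeak maps to `NA`.
#'
#' @param isotopologue Character vector of isotopologue labels.
#' @return Character vector of element labels (same as the input for rare
#'   species) with `NA` for the basepeak.
#' @export
isotopologue_element <- function(isotopologue) {
  out <- ifelse(isotopologue %in% names(ELEMENT_OF),
                unname(ELEMENT_OF[isotopologue]), NA_character_)
  out
}

# Natural-abundance isotopologue/basepeak ratio for a singly substituted
# species: n * p / (1 - p) with n substitutable atoms and atom fraction p.
# Exact under the binomial (stochastic) isotopologue distribution.
natural_ratio <- function(specs) {
  stopifnot(is.data.frame(specs))
  rare <- dplyr::filter(specs, !.data$is_basepeak)
  base <- dplyr::filter(specs, .data$is_basepeak)
  n_atoms <- function(formula, major_nuclide, rare_nuclide) {
    atoms <- parse_isotopic_formula(formula)
    sum(atoms$count[atoms$nuclide %in% c(major_nuclide, rare_nuclide)])
  }
  ratios <- purrr::map_dbl(seq_len(nrow(rare)), function(i) {
    iso <- rare$isotopologue[i]
    if (!iso %in% names(ISOTOPE_ATOM_FRACTION)) {
      abort(paste0("No abundance data for isotopologue label: ", iso))
    }
    p <- ISOTOPE_ATOM_FRACTION[[iso]]
    base_formula <- base$isotopic_formula[base$fragment_id == rare$fragment_id[i]]
    n <- n_atoms(base_formula, MAJOR_OF[[iso]], iso)
    n * p / (1 - p)
  })
  tibble(
    fragment_id = rare$fragment_id,
    isotopologue = rare$isotopologue,
    ratio_natural = ratios
  )
}
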