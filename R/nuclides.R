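# Atomic masses (u) from the AME2020 atomic-mass evaluation; neutral atoms.
NUCLIDE_MASS <- c(
  "1H"  = 1.00782503224,
  "2H"  = 2.01410177811,
  "12C" = 12.0,
  "13C" = 13.00335483521,
  "14N" = 14.00307400446,
  "15N" = 15.00010889894,
  "16O" = 15.99491461960,
  "17O" = 16.99913175664,
  "18O" = 17.99915961284,
  "32S" = 31.97207117443,
  "33S" = 32.97145890985,
  "34S" = 33.96786701200,
  "36S" = 35.96708070720
)

ELECTRON_MASS <- 0.000548579909

# Representative terrestrial isotopic atom fractions (IUPAC).
ISOTOPE_ATOM_FRACTION <- c(
  "13C" = 0.0107,
  "15N" = 0.00364,
  "33S" = 0.0075,
  "34S" = 0.0425
)

MAJOR_OF <- c("13C" = "12C", "15N" = "14N", "33S" = "32S", "34S" = "32S")

ELEMENT_OF <- c("13C" = "13C", "15N" = "15N", "33S" = "33S", "34S" = "34S")

#' Parse an isotopic formula string
#'
#' Formulas name each nuclide explicitly, e.g. `"13C1 12C3 1H7 14N2 16O1"`.
#' A missing trailing count means 1.
#'
#' @param formula A single string of whitespace-separated `<mass><symbol><count>`
#'   tokens.
#' @return A tibble with columns `nuclide` and `count`.
#' @examples
#' parse_isotopic_formula("12C4 1H7 14N2 16O")
#' @export
parse_isotopic_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1)
  tokens <- strsplit(trimws(formula), "\\s+")[[1]]
  if (length(tokens) == 0) abort("Empty isotopic formula.")
  m <- regmatches(tokens, regexec("^([0-9]+[A-Z][a-z]?)([0-9]*)$", tokens))
  bad <- vapply(m, function(x) length(x) == 0, logical(1))
  if (any(bad)) {
    abort(paste0("Cannot parse formula token(s): ",
                 paste(tokens[bad], collapse = ", ")))
  }
  tibble(
    nuclide = vapply(m, `[`, character(1), 2),
    count = vapply(m, function(x) {
      if (x[3] == "") 1L else as.integer(x[3])
    }, integer(1))
  )
}

#' Exact mass-to-charge ratio of an isotopologue
#'
#' Sums nuclide masses over the isotopic formula and corrects for the
#' electron gained or lost on ionization: one electron mass is subtracted
#' for positive ions and added for negative ions. When the spec row carries
#' a nominal `mz`, the computed value is checked against it and a mismatch
#' beyond `tol` raises a warning (nominal extraction masses occasionally
#' disagree with masses computed from standard atomic-mass tables).
#'
#' @param spec A one-row data frame with columns `isotopic_formula` and
#'   `polarity` (and optionally `mz`), or a formula string plus `polarity`.
#' @param polarity `"positive"`, `"negative"` or `"neutral"`; ignored when
#'   `spec` is a data frame.
#' @param tol Tolerance for the nominal-mass consistency check, in u.
#' @return The exact m/z (z = 1) as a number.
#' @examples
#' exact_mass("12C4 1H7 14N2 16O", polarity = "positive")
#' @export
exact_mass <- function(spec, polarity = "neutral", tol = 0.001) {
  nominal <- NA_real_
  if (is.data.frame(spec)) {
    stopifnot(nrow(spec) == 1)
    formula <- spec$isotopic_formula
    polarity <- spec$polarity
    if ("mz" %in% names(spec)) nominal <- spec$mz
  } else {
    formula <- spec
  }
  atoms <- parse_isotopic_formula(formula)
  unknown <- setdiff(atoms$nuclide, names(NUCLIDE_MASS))
  if (length(unknown) > 0) {
    abort(paste0("Unknown nuclide(s): ", paste(unknown, collapse = ", ")))
  }
  mass <- sum(NUCLIDE_MASS[atoms$nuclide] * atoms$count)
  mass <- mass + switch(polarity,
    positive = -ELECTRON_MASS,
    negative = +ELECTRON_MASS,
    neutral = 0,
    abort("`polarity` must be 'positive', 'negative' or 'neutral'.")
  )
  if (is.finite(nominal) && abs(mass - nominal) > tol) {
    warn(sprintf(
      "Computed m/z %.4f differs from nominal %.4f by more than %.4g u.",
      mass, nominal, tol
    ))
  }
  mass
}
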