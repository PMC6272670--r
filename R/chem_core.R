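# Monoisotopic masses of the most abundant isotope of each supported element.
# The alphabet (C, H, N, O, Na) covers every neutral and ion composition that
# occurs in dibenzylbutyrolactone lignan chemistry in positive-ion ESI.
.element_masses <- c(
  C  = 12,
  H  = 1.0078250,
  N  = 14.0030740,
  O  = 15.9949146,
  Na = 22.9897693
)

# Supported positive-mode adducts. Ion m/z is computed WITHOUT subtracting the
# electron mass: this matches the precursor arithmetic of the reference tables
# (e.g. sodiated C32H42O16 at 705.2371) even though a few printed fragment
# constants follow the electron-corrected convention; those are therefore
# stored as printed constants in fragment_rules() rather than recomputed.
.adducts <- list(
  "[M+H]+"  = list(delta = c(H = 1),  charge = 1L),
  "[M+Na]+" = list(delta = c(Na = 1), charge = 1L)
)

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention used for
#' all reported m/z and ppm values), unlike [base::round()] which rounds half
#' to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return `x` rounded to `digits` decimals.
#' @examples
#' round_half_up(2.5, 0)   # 3
#' round_half_up(-2.925, 2)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

new_elemental_formula <- function(counts) {
  counts <- counts[counts != 0]
  if (length(counts)) {
    # Hill order: C, H, then remaining elements alphabetically
    rest <- sort(setdiff(names(counts), c("C", "H")))
    counts <- counts[intersect(c("C", "H", rest), names(counts))]
  }
  structure(as.numeric(counts), names = names(counts),
            class = "elemental_formula")
}

#' Parse an elemental formula string
#'
#' Parses strings such as `"C26H32O12"` into an `elemental_formula` object,
#' a named vector of non-negative element counts. Only C, H, O, N and Na are
#' accepted. The canonical formatting (see [format_formula()]) uses Hill
#' order: C, H, then remaining elements alphabetically.
#'
#' @param text A formula string: element symbols each followed by an optional
#'   positive integer count.
#' @return An `elemental_formula` object.
#' @examples
#' parse_formula("C26H32O12")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(new_elemental_formula(numeric(0)))
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    stop("malformed formula string: '", text, "'")
  }
  counts <- c(C = 0, H = 0, N = 0, O = 0, Na = 0)
  for (tok in tokens) {
    sym <- sub("[0-9]*$", "", tok)
    num <- sub("^[A-Za-z]+", "", tok)
    if (!sym %in% names(.element_masses)) {
      stop("unknown element symbol: '", sym, "'")
    }
    n <- if (nzchar(num)) as.numeric(num) else 1
    if (n <= 0 || n != floor(n)) stop("malformed count in '", tok, "'")
    counts[sym] <- counts[sym] + n
  }
  new_elemental_formula(counts)
}

#' Coerce to an elemental formula
#'
#' @param x A formula string or an `elemental_formula`.
#' @return An `elemental_formula` object.
#' @export
as_formula <- function(x) {
  if (inherits(x, "elemental_formula")) return(x)
  if (is.character(x)) return(parse_formula(x))
  stop("cannot coerce object of class '", class(x)[1], "' to a formula")
}

#' Format an elemental formula in Hill order
#'
#' @param f An `elemental_formula` (or formula string).
#' @return A single string, e.g. `"C26H32O12"`; counts of 1 are implicit.
#' @export
format_formula <- function(f) {
  f <- as_formula(f)
  if (!length(f)) return("")
  paste0(names(f), ifelse(f == 1, "", f), collapse = "")
}

#' @export
format.elemental_formula <- function(x, ...) format_formula(x)

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<formula> ", format_formula(x), "  (",
      sprintf("%.4f", monoisotopic_mass(x)), " Da)\n", sep = "")
  invisible(x)
}

#' @export
`+.elemental_formula` <- function(e1, e2) {
  e1 <- as_formula(e1); e2 <- as_formula(e2)
  els <- union(names(e1), names(e2))
  out <- setNames(numeric(length(els)), els)
  out[names(e1)] <- out[names(e1)] + as.numeric(e1)
  out[names(e2)] <- out[names(e2)] + as.numeric(e2)
  new_elemental_formula(out)
}

#' @export
`-.elemental_formula` <- function(e1, e2) {
  e1 <- as_formula(e1); e2 <- as_formula(e2)
  els <- union(names(e1), names(e2))
  out <- setNames(numeric(length(els)), els)
  out[names(e1)] <- out[names(e1)] + as.numeric(e1)
  out[names(e2)] <- out[names(e2)] - as.numeric(e2)
  if (any(out < 0)) {
    stop("formula subtraction would give a negative count for: ",
         paste(names(out)[out < 0], collapse = ", "))
  }
  new_elemental_formula(out)
}

#' Monoisotopic mass of a formula
#'
#' Sum over elements of count times the mass of the most abundant isotope
#' (C 12 exactly, H 1.0078250, O 15.9949146, N 14.0030740, Na 22.9897693).
#' Additive: `monoisotopic_mass(f1 + f2)` equals the sum of the parts.
#'
#' @param f An `elemental_formula` or formula string.
#' @return Mass in Da (full double precision; use [round_half_up()] with 4
#'   digits for reporting).
#' @examples
#' monoisotopic_mass("C6H10O5")  # glucose residue, 162.0528
#' @export
monoisotopic_mass <- function(f) {
  f <- as_formula(f)
  if (!length(f)) return(0)
  sum(as.numeric(f) * .element_masses[names(f)])
}

#' Supported adducts
#'
#' @return Character vector of supported adduct names.
#' @export
adduct_names <- function() names(.adducts)

adduct_info <- function(adduct) {
  if (!adduct %in% names(.adducts)) {
    stop("unsupported adduct '", adduct, "'; supported: ",
         paste(names(.adducts), collapse = ", "))
  }
  .adducts[[adduct]]
}

#' Theoretical m/z of a singly charged adduct ion
#'
#' Computes the monoisotopic mass of the neutral molecule plus the adduct
#' species (`[M+H]+` adds H, `[M+Na]+` adds Na). No electron-mass correction
#' is applied; reported values are conventionally rounded half-up to 4
#' decimal places.
#'
#' @param f Neutral molecule, as `elemental_formula` or string.
#' @param adduct Adduct name, `"[M+H]+"` or `"[M+Na]+"`.
#' @return m/z in Da at full precision.
#' @examples
#' round_half_up(ion_mz("C32H42O17", "[M+Na]+"), 4)  # 721.2320
#' @export
ion_mz <- function(f, adduct = "[M+H]+") {
  a <- adduct_info(adduct)
  monoisotopic_mass(as_formula(f) + new_elemental_formula(a$delta))
}

#' Parts-per-million mass error
#'
#' `(measured - reference) / reference * 1e6`, rounded half away from zero to
#' `digits` decimals (2 by default, the reporting convention).
#'
#' @param measured Measured m/z (Da); vectorised.
#' @param reference Theoretical/calculated m/z (Da), must be positive.
#' @param digits Decimals to round to, or `NULL` for the unrounded value.
#' @return Signed ppm error.
#' @examples
#' ppm_error(137.0599, 137.0603)  # -2.92
#' @export
ppm_error <- function(measured, reference, digits = 2) {
  if (any(reference <= 0)) stop("reference m/z must be positive")
  ppm <- (measured - reference) / reference * 1e6
  if (is.null(digits)) ppm else round_half_up(ppm, digits)
}

#' Ring-plus-double-bond equivalents
#'
#' `C - H/2 + N/2 + 1` for CHNO formulas; Na is treated like H (it caps a
#' valence), contributing -1/2.
#'
#' @param f An `elemental_formula` or formula string.
#' @return RDBE as a numeric (integer or half-integer for valid formulas).
#' @examples
#' rdbe("C26H32O12")  # 11
#' rdbe("C6H6")       # 4
#' @export
rdbe <- function(f) {
  f <- as_formula(f)
  cnt <- function(el) if (el %in% names(f)) f[[el]] else 0
  cnt("C") - (cnt("H") + cnt("Na")) / 2 + cnt("N") / 2 + 1
}

#' Neutral-loss reference table
#'
#' The neutral losses recognised by the annotator: sugar residues (Glc, Rha,
#' Api), small molecules (H2O, CO, HCOH, CH3COOH), the quinone-methide
#' neutral of ring A (the loss behind \eqn{[M+H-A]^+}), and the cross-ring
#' C2H4O2 fragment of C-glycosides (nominally "-60").
#'
#' @return A data frame with columns `name`, `formula`, `nominal_da`,
#'   `mass_da`.
#' @export
neutral_losses <- function() {
  df <- data.frame(
    name = c("Glc", "Rha", "Api", "H2O", "CO", "HCOH", "CH3COOH",
             "A-quinone-methide", "cross-ring-C2H4O2"),
    formula = c("C6H10O5", "C6H10O4", "C5H8O4", "H2O", "CO", "CH2O",
                "C2H4O2", "C8H8O2", "C2H4O2"),
    nominal_da = c(162L, 146L, 132L, 18L, 28L, 30L, 60L, 136L, 60L),
    stringsAsFactors = FALSE
  )
  df$mass_da <- vapply(df$formula, function(x) monoisotopic_mass(x), 0)
  df
}
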