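#' Enumerate candidate molecular formulas for an accurate mass
#'
#' Exhaustive search of the bounded C/H/O/N lattice for neutral formulas
#' whose adduct ion matches a measured m/z within a ppm tolerance. This is
#' the formula-deduction step used to assign precursor compositions from
#' accurate QTOF masses. The default bounds (C 0-40, H 0-60, O 0-20, no
#' nitrogen) cover lignan glycosides up to di-hexosides; the lattice is about
#' 50k points, so plain enumeration is instantaneous and no heuristic
#' filtering beyond RDBE and the H <= 2C+2 valence cap is applied.
#'
#' Candidates are sorted by increasing absolute ppm error; ties are broken by
#' closeness of RDBE to 10 (the typical value for these aglycones) and then
#' lexicographically by formula.
#'
#' @param mz Measured ion m/z (Da), positive.
#' @param adduct Adduct hypothesis, `"[M+H]+"` or `"[M+Na]+"`.
#' @param tol_ppm Match tolerance in ppm (default 10, which accommodates the
#'   largest precursor deviations seen on a routinely calibrated QTOF).
#' @param bounds Named list of `c(min, max)` element-count bounds for C, H,
#'   O, N.
#' @param rdbe_range Allowed ring-plus-double-bond-equivalent range.
#' @return A data frame (possibly 0-row) with columns `formula`, `C`, `H`,
#'   `N`, `O`, `theoretical_mz`, `ppm`, `rdbe`.
#' @examples
#' head(enumerate_formulas(559.1792, "[M+Na]+", tol_ppm = 5))
#' @export
enumerate_formulas <- function(mz, adduct = "[M+H]+", tol_ppm = 10,
                               bounds = list(C = c(0, 40), H = c(0, 60),
                                             O = c(0, 20), N = c(0, 0)),
                               rdbe_range = c(0, 25)) {
  stopifnot(is.numeric(mz), length(mz) == 1L, mz > 0, tol_ppm > 0)
  for (el in c("C", "H", "O", "N")) {
    if (is.null(bounds[[el]])) bounds[[el]] <- c(0, 0)
    b <- bounds[[el]]
    if (length(b) != 2L || b[1] > b[2] || b[1] < 0) {
      stop("invalid bounds for element ", el)
    }
  }
  a <- adduct_info(adduct)
  adduct_mass <- monoisotopic_mass(new_elemental_formula(a$delta))

  grid <- expand.grid(
    C = seq(bounds$C[1], bounds$C[2]),
    H = seq(bounds$H[1], bounds$H[2]),
    O = seq(bounds$O[1], bounds$O[2]),
    N = seq(bounds$N[1], bounds$N[2]),
    KEEP.OUT.ATTRS = FALSE
  )
  m <- .element_masses
  theo <- grid$C * m[["C"]] + grid$H * m[["H"]] + grid$O * m[["O"]] +
    grid$N * m[["N"]] + adduct_mass
  ppm <- (mz - theo) / theo * 1e6
  rd <- grid$C - grid$H / 2 + grid$N / 2 + 1

  keep <- abs(ppm) <= tol_ppm &
    (grid$C + grid$H + grid$O + grid$N) > 0 &
    grid$H <= 2 * grid$C + 2 &
    rd >= rdbe_range[1] & rd <= rdbe_range[2] &
    (2 * rd) == floor(2 * rd)
  if (!any(keep)) {
    return(data.frame(formula = character(0), C = integer(0), H = integer(0),
                      N = integer(0), O = integer(0),
                      theoretical_mz = numeric(0), ppm = numeric(0),
                      rdbe = numeric(0), stringsAsFactors = FALSE))
  }
  grid <- grid[keep, , drop = FALSE]
  theo <- theo[keep]; ppm <- ppm[keep]; rd <- rd[keep]

  fstr <- vapply(seq_len(nrow(grid)), function(i) {
    format_formula(new_elemental_formula(c(C = grid$C[i], H = grid$H[i],
                                           N = grid$N[i], O = grid$O[i])))
  }, "")
  ord <- order(abs(ppm), abs(rd - 10), fstr)
  data.frame(
    formula = fstr[ord],
    C = grid$C[ord], H = grid$H[ord], N = grid$N[ord], O = grid$O[ord],
    theoretical_mz = theo[ord],
    ppm = round_half_up(ppm[ord], 2),
    rdbe = rd[ord],
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
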