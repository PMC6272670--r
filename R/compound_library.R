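.subclass_levels <- c("lignano-9,9'-lactone",
                      "lignano-8'-hydroxy-9,9'-lactone",
                      "other")

.lt_cache <- new.env(parent = emptyenv())

#' Build the 25-compound reference library
#'
#' Loads the versioned JSON resource shipped with the package: the 14
#' quantified dibenzylbutyrolactone lignan standards, tanegoside A, and the
#' ten further constituents detected in Caulis Trachelospermi, each with its
#' neutral formula, lignan subclass, aromatic-ring substitution tags and
#' ordered sugar list.
#'
#' @return A `lignan_library` object: a list of 25 `compound_record`s, each
#'   with fields `id`, `name`, `formula` (an `elemental_formula`),
#'   `subclass`, `ring_A`, `ring_Aprime` and `sugars` (a data frame with
#'   columns `residue`, `linkage`).
#' @examples
#' lib <- build_library()
#' lib[[12]]$subclass   # trachelogenin
#' @export
build_library <- function() {
  if (!is.null(.lt_cache$library)) return(.lt_cache$library)
  path <- system.file("extdata", "lignan_library.json",
                      package = "lignantools", mustWork = TRUE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  records <- lapply(raw$compounds, function(x) {
    sugars <- if (length(x$sugars)) {
      data.frame(
        residue = vapply(x$sugars, `[[`, "", "residue"),
        linkage = vapply(x$sugars, `[[`, "", "linkage"),
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(residue = character(0), linkage = character(0),
                 stringsAsFactors = FALSE)
    }
    stopifnot(x$subclass %in% .subclass_levels)
    structure(
      list(id = as.integer(x$id), name = x$name,
           formula = parse_formula(x$formula), subclass = x$subclass,
           ring_A = x$ring_A, ring_Aprime = x$ring_Aprime, sugars = sugars),
      class = "compound_record"
    )
  })
  lib <- structure(records, class = "lignan_library",
                   version = raw$library_version)
  .lt_cache$library <- lib
  lib
}

#' @export
print.compound_record <- function(x, ...) {
  cat(sprintf("<compound %d> %s  %s  [%s]\n", x$id, x$name,
              format_formula(x$formula), x$subclass))
  invisible(x)
}

#' @export
print.lignan_library <- function(x, ...) {
  cat("<lignan_library> v", attr(x, "version"), ", ",
      length(x), " compounds\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.lignan_library <- function(x, ...) {
  data.frame(
    id = vapply(x, `[[`, 0L, "id"),
    name = vapply(x, `[[`, "", "name"),
    formula = vapply(x, function(r) format_formula(r$formula), ""),
    subclass = vapply(x, `[[`, "", "subclass"),
    ring_A = vapply(x, `[[`, "", "ring_A"),
    ring_Aprime = vapply(x, `[[`, "", "ring_Aprime"),
    sugars = vapply(x, function(r) {
      if (!nrow(r$sugars)) "" else
        paste0(r$sugars$residue, "(", r$sugars$linkage, ")", collapse = ",")
    }, ""),
    stringsAsFactors = FALSE
  )
}

#' Aglycone formula of a library compound
#'
#' The neutral formula minus one residue (e.g. C6H10O5 per Glc) for each
#' O-linked sugar. C-linked sugars are not removable by glycosidic cleavage
#' and stay part of the aglycone.
#'
#' @param record A `compound_record`.
#' @return An `elemental_formula`.
#' @export
aglycone_formula <- function(record) {
  stopifnot(inherits(record, "compound_record"))
  f <- record$formula
  losses <- neutral_losses()
  sug <- record$sugars
  for (i in seq_len(nrow(sug))) {
    if (sug$linkage[i] == "O") {
      f <- f - losses$formula[match(sug$residue[i], losses$name)]
    }
  }
  f
}

#' Diagnostic fragment-rule table
#'
#' The named benzyl-cation and lactone-ion rules of the lignan fragmentation
#' scheme. Reference m/z values for rules that appear in the printed
#' reference tables are stored as those printed constants (the tables mix
#' electron-corrected and uncorrected conventions, so report parity requires
#' constants, not recomputation); rules without a printed constant carry the
#' uncorrected computed mass of their ion formula. Either way the ion-formula
#' mass agrees with `reference_mz` within 1.0 mDa.
#'
#' @return A data frame with columns `label`, `ring`, `subclass`
#'   (`"both"` or a specific subclass), `reference_mz`, `ion_formula`,
#'   `source` (`"printed"` or `"computed"`).
#' @export
fragment_rules <- function() {
  if (!is.null(.lt_cache$rules)) return(.lt_cache$rules)
  .lt_cache$rules <- data.frame(
    label = c("[A]+", "[A']+", "[A']+", "[A']+",
              "[B]+", "[B]+", "[B]+",
              "[C+H]+", "[C+H]+", "[C+H]+",
              "[A-H+Na]+"),
    ring = c("guaiacyl", "guaiacyl", "veratryl", "methoxy-veratryl",
             "guaiacyl", "veratryl", "methoxy-veratryl",
             "guaiacyl", "veratryl", "methoxy-veratryl",
             "guaiacyl"),
    subclass = c("both", "both", "both", "both",
                 "lignano-9,9'-lactone", "lignano-9,9'-lactone",
                 "lignano-9,9'-lactone",
                 "lignano-8'-hydroxy-9,9'-lactone",
                 "lignano-8'-hydroxy-9,9'-lactone",
                 "lignano-8'-hydroxy-9,9'-lactone",
                 "both"),
    reference_mz = c(137.0603, 137.0603, 151.0754, 181.0859,
                     163.0754, 177.0910, 207.1021,
                     233.0808, 247.0965, 277.1076,
                     159.0417),
    ion_formula = c("C8H9O2", "C8H9O2", "C9H11O2", "C10H13O3",
                    "C10H11O2", "C11H13O2", "C12H15O3",
                    "C13H13O4", "C14H15O4", "C15H17O5",
                    "C8H8O2Na"),
    source = c("printed", "printed", "printed", "printed",
               "printed", "printed", "computed",
               "printed", "printed", "computed",
               "printed"),
    stringsAsFactors = FALSE
  )
  .lt_cache$rules
}

rule_mz <- function(label, ring) {
  rules <- fragment_rules()
  hit <- rules$label == label & rules$ring == ring
  if (!any(hit)) stop("no fragment rule for ", label, " / ", ring)
  rules$reference_mz[which(hit)[1]]
}

#' Expected diagnostic ions for a library compound
#'
#' Applies the fragmentation scheme forward to one compound under a given
#' precursor adduct:
#' \itemize{
#'   \item lignano-9,9'-lactones: \eqn{[A]^+}, \eqn{[A']^+}, \eqn{[B]^+}
#'     (from ring A'), and the complement \eqn{[M+H-A]^+} (protonated
#'     aglycone minus the 136.0524 quinone-methide neutral);
#'   \item lignano-8'-hydroxy-9,9'-lactones: \eqn{[M+H-H_2O]^+} of the
#'     aglycone, \eqn{[A]^+}, \eqn{[A']^+}, and \eqn{[C+H]^+} (from ring A');
#'   \item any O-glycoside: the sequential sugar-loss ladder from the
#'     precursor down to the (de)glycosylated aglycone ion, one further water
#'     loss from the terminal ladder node, and \eqn{[A-H+Na]^+} when the
#'     precursor is sodiated;
#'   \item C-glycosides: the cross-ring cleavage ions
#'     \eqn{[M+H-2H_2O-60]^+} and \eqn{[M+H-3H_2O-60]^+}.
#' }
#' Compounds of subclass `"other"` only produce their neutral-loss ladder.
#' Rules are a property of the structure; whether an ion is observed is a
#' property of the spectrum.
#'
#' @param record A `compound_record`.
#' @param adduct Precursor adduct, `"[M+H]+"` or `"[M+Na]+"`.
#' @return A data frame with columns `label`, `mz`, `source` (`"rule"` for
#'   subclass ions at printed-constant masses, `"loss"` for computed
#'   ladder/loss ions).
#' @examples
#' lib <- build_library()
#' diagnostic_fragments(lib[[11]], "[M+H]+")  # matairesinol
#' @export
diagnostic_fragments <- function(record, adduct = "[M+Na]+") {
  stopifnot(inherits(record, "compound_record"))
  a <- adduct_info(adduct)  # validates the adduct
  losses <- neutral_losses()
  loss_mass <- function(nm) losses$mass_da[match(nm, losses$name)]

  lab <- character(0); mz <- numeric(0); src <- character(0)
  add <- function(l, m, s) {
    lab <<- c(lab, l); mz <<- c(mz, m); src <<- c(src, s)
  }

  precursor <- ion_mz(record$formula, adduct)
  agl <- aglycone_formula(record)
  agl_mh <- ion_mz(agl, "[M+H]+")

  if (record$subclass == "lignano-9,9'-lactone") {
    add("[A]+", rule_mz("[A]+", record$ring_A), "rule")
    add("[A']+", rule_mz("[A']+", record$ring_Aprime), "rule")
    add("[B]+", rule_mz("[B]+", record$ring_Aprime), "rule")
    add("[M+H-A]+", agl_mh - loss_mass("A-quinone-methide"), "loss")
  } else if (record$subclass == "lignano-8'-hydroxy-9,9'-lactone") {
    add("[M+H-H2O]+", agl_mh - loss_mass("H2O"), "loss")
    add("[A]+", rule_mz("[A]+", record$ring_A), "rule")
    add("[A']+", rule_mz("[A']+", record$ring_Aprime), "rule")
    add("[C+H]+", rule_mz("[C+H]+", record$ring_Aprime), "rule")
  }

  sug <- record$sugars
  o_sugars <- sug$residue[sug$linkage == "O"]
  if (length(o_sugars)) {
    stub <- sub("\\]\\+$", "", adduct)  # "[M+H" / "[M+Na"
    running <- precursor
    trail <- character(0)
    for (res in o_sugars) {
      running <- running - loss_mass(res)
      trail <- c(trail, res)
      add(paste0(stub, "-", paste(trail, collapse = "-"), "]+"),
          running, "loss")
    }
    add(paste0(stub, "-", paste(trail, collapse = "-"), "-H2O]+"),
        running - loss_mass("H2O"), "loss")
    if (adduct == "[M+Na]+") {
      add("[A-H+Na]+", rule_mz("[A-H+Na]+", "guaiacyl"), "rule")
    }
  }

  if (any(sug$linkage == "C")) {
    mh <- ion_mz(record$formula, "[M+H]+")
    cr <- loss_mass("cross-ring-C2H4O2")
    w <- loss_mass("H2O")
    add("[M+H-2H2O-60]+", mh - 2 * w - cr, "loss")
    add("[M+H-3H2O-60]+", mh - 3 * w - cr, "loss")
  }

  out <- data.frame(label = lab, mz = mz, source = src,
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out$label) & out$mz > 0, , drop = FALSE]
  row.names(out) <- NULL
  out
}
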