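#' Construct a centroided MS/MS spectrum
#'
#' Container for a precursor and its centroided fragment peak list. Peaks are
#' sorted by m/z and made unique at 4 decimal places (duplicates collapse to
#' the more intense centroid). The precursor must sit at or above the highest
#' fragment (minus a 0.01 Da guard).
#'
#' @param precursor_mz Precursor ion m/z (Da).
#' @param mz Numeric vector of fragment m/z values (Da, all positive).
#' @param intensity Optional intensities (arbitrary units, >= 0); default 1.
#'   Intensities are carried through but ignored by matching and scoring.
#' @param adduct Adduct hypothesis (`"[M+H]+"`, `"[M+Na]+"`) or `NA` if
#'   unknown.
#' @param label Optional true compound id (used by the simulator).
#' @return An `ms2_spectrum` object with fields `precursor_mz`, `adduct`,
#'   `label` and `peaks` (data frame `mz`, `intensity`).
#' @export
ms2_spectrum <- function(precursor_mz, mz, intensity = NULL,
                         adduct = NA_character_, label = NA_integer_) {
  stopifnot(is.numeric(precursor_mz), length(precursor_mz) == 1L,
            precursor_mz > 0)
  mz <- as.numeric(mz)
  if (any(mz <= 0)) stop("fragment m/z values must be positive")
  if (is.null(intensity)) intensity <- rep(1, length(mz))
  if (length(intensity) != length(mz)) {
    stop("mz and intensity lengths differ")
  }
  if (any(intensity < 0)) stop("intensities must be non-negative")
  if (length(mz) && precursor_mz < max(mz) - 0.01) {
    stop("precursor m/z below the highest fragment peak")
  }
  if (!is.na(adduct)) adduct_info(adduct)
  key <- round_half_up(mz, 4)
  ord <- order(key, -intensity)
  mz <- mz[ord]; intensity <- intensity[ord]; key <- key[ord]
  keep <- !duplicated(key)
  structure(
    list(precursor_mz = precursor_mz, adduct = adduct,
         label = as.integer(label),
         peaks = data.frame(mz = mz[keep], intensity = intensity[keep])),
    class = "ms2_spectrum"
  )
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("<ms2_spectrum> precursor %.4f %s, %d peaks%s\n",
              x$precursor_mz,
              if (is.na(x$adduct)) "(adduct unknown)" else x$adduct,
              nrow(x$peaks),
              if (is.na(x$label)) "" else sprintf(", label %d", x$label)))
  invisible(x)
}

#' Match expected ions against a spectrum
#'
#' Greedy nearest-neighbour assignment of expected ions to measured peaks
#' within an absolute mDa tolerance. Candidate pairs are processed in order
#' of increasing absolute mass deviation (ties to the lower expected m/z);
#' each peak satisfies at most one expected ion and vice versa. An absolute
#' tolerance is used rather than ppm because the fragment deviations in this
#' chemistry are flat on the mDa scale, not proportional to mass.
#'
#' @param spectrum An `ms2_spectrum`.
#' @param expected Data frame of expected ions with columns `label`, `mz`
#'   (as produced by [diagnostic_fragments()]).
#' @param tol_mda Match tolerance in mDa (default 10).
#' @return Evidence data frame with columns `label`, `expected_mz`,
#'   `measured_mz`, `mda` (signed, full precision), `ppm` (2 dp). Unmatched
#'   expected ions are simply absent.
#' @export
match_peaks <- function(spectrum, expected, tol_mda = 10) {
  stopifnot(inherits(spectrum, "ms2_spectrum"), tol_mda > 0)
  empty <- data.frame(label = character(0), expected_mz = numeric(0),
                      measured_mz = numeric(0), mda = numeric(0),
                      ppm = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(expected) || !nrow(spectrum$peaks)) return(empty)

  pk <- spectrum$peaks$mz
  d <- outer(expected$mz, pk, function(e, p) p - e)
  idx <- which(abs(d) <= tol_mda / 1000, arr.ind = TRUE)
  if (!nrow(idx)) return(empty)

  cand <- data.frame(ei = idx[, 1], pi = idx[, 2],
                     adist = abs(d[idx]), delta = d[idx])
  cand <- cand[order(cand$adist, expected$mz[cand$ei], cand$ei), ]
  used_e <- rep(FALSE, nrow(expected))
  used_p <- rep(FALSE, length(pk))
  take <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    e <- cand$ei[k]; p <- cand$pi[k]
    if (!used_e[e] && !used_p[p]) {
      take[k] <- TRUE
      used_e[e] <- TRUE
      used_p[p] <- TRUE
    }
  }
  cand <- cand[take, , drop = FALSE]
  out <- data.frame(
    label = expected$label[cand$ei],
    expected_mz = expected$mz[cand$ei],
    measured_mz = pk[cand$pi],
    mda = cand$delta * 1000,
    ppm = ppm_error(pk[cand$pi], expected$mz[cand$ei]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$expected_mz), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Detect neutral-loss relationships in a spectrum
#'
#' Searches parent-to-child mass differences (precursor to peak, and peak to
#' peak) for matches to the known neutral losses. Sugar-residue losses (Glc,
#' Rha, Api) are restricted to a ladder of depth two starting at the
#' precursor; small-molecule losses (H2O, CO, HCOH, CH3COOH) and the
#' quinone-methide / cross-ring losses are allowed from any node.
#'
#' @param spectrum An `ms2_spectrum`.
#' @param tol_mda Tolerance in mDa on the mass difference (default 10).
#' @return Data frame with columns `loss`, `parent_mz`, `child_mz`, `mda`
#'   (signed deviation of the observed difference from the loss mass).
#' @export
detect_neutral_losses <- function(spectrum, tol_mda = 10) {
  stopifnot(inherits(spectrum, "ms2_spectrum"), tol_mda > 0)
  losses <- neutral_losses()
  sugar <- c("Glc", "Rha", "Api")
  tol <- tol_mda / 1000
  pk <- spectrum$peaks$mz
  pre <- spectrum$precursor_mz

  parents <- c(pre, pk)
  is_pre <- c(TRUE, rep(FALSE, length(pk)))
  out <- data.frame(loss = character(0), parent_mz = numeric(0),
                    child_mz = numeric(0), mda = numeric(0),
                    stringsAsFactors = FALSE)
  if (!length(pk)) return(out)

  # depth-1 sugar children of the precursor, for the depth <= 2 ladder rule
  depth1 <- pk[vapply(pk, function(p) {
    any(abs((pre - p) - losses$mass_da[match(sugar, losses$name)]) <= tol)
  }, TRUE)]

  for (i in seq_along(parents)) {
    par <- parents[i]
    kids <- pk[pk < par - 1e-9]
    if (!length(kids)) next
    for (j in seq_len(nrow(losses))) {
      dev <- (par - kids) - losses$mass_da[j]
      hit <- abs(dev) <= tol
      if (!any(hit)) next
      if (losses$name[j] %in% sugar) {
        # sugar losses only from the precursor or from a depth-1 sugar child
        ok <- is_pre[i] || any(abs(par - depth1) <= 1e-9)
        if (!ok) next
      }
      out <- rbind(out, data.frame(
        loss = losses$name[j], parent_mz = par, child_mz = kids[hit],
        mda = dev[hit] * 1000, stringsAsFactors = FALSE
      ))
    }
  }
  row.names(out) <- NULL
  out
}

# Targets whose presence distinguishes the two lactone subclasses.
classification_targets <- function() {
  if (!is.null(.lt_cache$class_targets)) return(.lt_cache$class_targets)
  rules <- fragment_rules()
  lib <- build_library()
  mha <- vapply(
    Filter(function(r) r$subclass == "lignano-9,9'-lactone", lib),
    function(r) {
      ion_mz(aglycone_formula(r), "[M+H]+") -
        monoisotopic_mass("C8H8O2")
    }, 0)
  .lt_cache$class_targets <- list(
    ch = rules$reference_mz[rules$label == "[C+H]+"],
    b = rules$reference_mz[rules$label == "[B]+"],
    mha = unique(unname(mha))
  )
  .lt_cache$class_targets
}

#' Classify the lignan subclass of a spectrum
#'
#' Decision rule: any \eqn{[C+H]^+}-family ion implies a
#' lignano-8'-hydroxy-9,9'-lactone; otherwise any \eqn{[B]^+}-family ion or
#' an \eqn{[M+H-A]^+}-consistent ion implies a lignano-9,9'-lactone;
#' otherwise the call is `"undetermined"`. The shared benzyl cations
#' \eqn{[A]^+}/\eqn{[A']^+} never decide the subclass on their own.
#'
#' @param spectrum An `ms2_spectrum`.
#' @param tol_mda Tolerance in mDa (default 10).
#' @return A list with `subclass_call` and `evidence` (data frame `family`,
#'   `target_mz`, `measured_mz`, `mda`).
#' @examples
#' s <- ms2_spectrum(389.16, c(137.0613, 151.0770, 247.0977))
#' classify_subclass(s)$subclass_call
#' @export
classify_subclass <- function(spectrum, tol_mda = 10) {
  stopifnot(inherits(spectrum, "ms2_spectrum"), tol_mda > 0)
  tg <- classification_targets()
  tol <- tol_mda / 1000
  pk <- spectrum$peaks$mz

  hits <- function(targets, family) {
    if (!length(pk) || !length(targets)) {
      return(data.frame(family = character(0), target_mz = numeric(0),
                        measured_mz = numeric(0), mda = numeric(0)))
    }
    d <- outer(targets, pk, function(t, p) p - t)
    idx <- which(abs(d) <= tol, arr.ind = TRUE)
    data.frame(family = rep(family, nrow(idx)),
               target_mz = targets[idx[, 1]],
               measured_mz = pk[idx[, 2]],
               mda = d[idx] * 1000, stringsAsFactors = FALSE)
  }
  ev_ch <- hits(tg$ch, "[C+H]+")
  ev_b <- rbind(hits(tg$b, "[B]+"), hits(tg$mha, "[M+H-A]+"))

  if (nrow(ev_ch)) {
    list(subclass_call = "lignano-8'-hydroxy-9,9'-lactone", evidence = ev_ch)
  } else if (nrow(ev_b)) {
    list(subclass_call = "lignano-9,9'-lactone", evidence = ev_b)
  } else {
    list(subclass_call = "undetermined",
         evidence = data.frame(family = character(0), target_mz = numeric(0),
                               measured_mz = numeric(0), mda = numeric(0)))
  }
}

#' Identify a compound from its MS/MS spectrum
#'
#' Matches a spectrum against the library: candidate compounds are filtered
#' by precursor mass (ppm tolerance against the theoretical adduct ion of
#' their neutral formula; both adducts are tried when the hypothesis is
#' unknown), each candidate is scored by the number of its expected
#' diagnostic/loss ions found in the spectrum, and the best-scoring compound
#' is reported. Ties are ordered by lower mean absolute mDa deviation, then
#' by lower compound id; candidates with identical evidence (positional
#' isomers such as the nortrachelogenin monoglucosides) remain in the
#' reported tie set -- the mass spectrometric evidence cannot split them, and
#' retention behaviour is deliberately outside this scoring. A user-supplied
#' elution order (`rt_order`) annotates, but never re-ranks, the tie set.
#'
#' @param spectrum An `ms2_spectrum`.
#' @param library A `lignan_library` (default [build_library()]).
#' @param tol_mda Fragment match tolerance in mDa (default 10).
#' @param precursor_tol_ppm Precursor tolerance in ppm (default 10).
#' @param rt_order Optional integer vector of compound ids in elution order.
#' @return An `annotation_result`: list with `subclass_call`, `best_match`
#'   (compound id or `NA`), `tie_ids`, `score`, `evidence` (for the best
#'   candidate), `candidates` (per-candidate summary), `unexplained`
#'   (peaks not used as evidence for the best match), and `rt_annotation`.
#' @export
identify_spectrum <- function(spectrum, library = build_library(),
                              tol_mda = 10, precursor_tol_ppm = 10,
                              rt_order = NULL) {
  stopifnot(inherits(spectrum, "ms2_spectrum"))
  adducts <- if (!is.na(spectrum$adduct)) spectrum$adduct else adduct_names()

  cand <- list()
  for (rec in library) {
    for (ad in adducts) {
      pre_ppm <- ppm_error(spectrum$precursor_mz,
                           ion_mz(rec$formula, ad), digits = NULL)
      if (abs(pre_ppm) > precursor_tol_ppm) next
      ev <- match_peaks(spectrum, diagnostic_fragments(rec, ad), tol_mda)
      cand[[length(cand) + 1L]] <- list(
        id = rec$id, adduct = ad, precursor_ppm = pre_ppm,
        score = nrow(ev),
        mean_mda = if (nrow(ev)) mean(abs(ev$mda)) else Inf,
        evidence = ev
      )
    }
  }

  subclass <- classify_subclass(spectrum, tol_mda)
  res <- list(subclass_call = subclass$subclass_call,
              best_match = NA_integer_, tie_ids = integer(0),
              score = 0L,
              evidence = match_peaks(spectrum,
                                     data.frame(label = character(0),
                                                mz = numeric(0)), tol_mda),
              candidates = data.frame(id = integer(0), adduct = character(0),
                                      precursor_ppm = numeric(0),
                                      score = integer(0),
                                      mean_mda = numeric(0)),
              unexplained = spectrum$peaks,
              rt_annotation = integer(0))
  class(res) <- "annotation_result"
  if (!length(cand)) return(res)

  res$candidates <- data.frame(
    id = vapply(cand, `[[`, 0L, "id"),
    adduct = vapply(cand, `[[`, "", "adduct"),
    precursor_ppm = round_half_up(vapply(cand, `[[`, 0, "precursor_ppm"), 2),
    score = vapply(cand, `[[`, 0L, "score"),
    mean_mda = vapply(cand, `[[`, 0, "mean_mda"),
    stringsAsFactors = FALSE
  )
  scores <- res$candidates$score
  if (max(scores) == 0L) return(res)

  ord <- order(-scores, res$candidates$mean_mda, res$candidates$id)
  best <- cand[[ord[1]]]
  top <- ord[scores[ord] == best$score &
               abs(res$candidates$mean_mda[ord] - best$mean_mda) <= 1e-9]
  res$best_match <- best$id
  res$tie_ids <- sort(unique(res$candidates$id[top]))
  res$score <- best$score
  res$evidence <- best$evidence
  res$unexplained <- spectrum$peaks[
    !round_half_up(spectrum$peaks$mz, 4) %in%
      round_half_up(best$evidence$measured_mz, 4), , drop = FALSE]
  if (!is.null(rt_order)) {
    res$rt_annotation <- rt_order[rt_order %in% res$tie_ids]
  }
  res
}

#' @export
print.annotation_result <- function(x, ...) {
  cat("<annotation_result>\n")
  cat("  subclass:", x$subclass_call, "\n")
  if (is.na(x$best_match)) {
    cat("  best match: none\n")
  } else {
    cat(sprintf("  best match: compound %d (score %d)%s\n", x$best_match,
                x$score,
                if (length(x$tie_ids) > 1)
                  paste0(", tie set {", paste(x$tie_ids, collapse = ","), "}")
                else ""))
  }
  if (nrow(x$evidence)) {
    print(transform(x$evidence, mda = round_half_up(mda, 2)),
          row.names = FALSE)
  }
  invisible(x)
}
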