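#' Solvent surface-form lexicon
#'
#' Maps the surface forms that occur in raw patent purification text
#' (synonyms, abbreviations, spacing variants) onto the ten canonical solvent
#' labels. Matching is case-insensitive and longest-match-first, so
#' "methanol" is never double-counted as "ethanol" and "diethyl ether" never
#' as plain "ethyl ether". Unknown solvents outside the closed 10-label set
#' are deliberately absent: mentions of them do not expand the label space,
#' they simply never match.
#'
#' @return Tibble with columns `surface` and `canonical`.
#' @export
solvent_lexicon <- function() {
  lex <- list(
    "ethyl acetate" = c("ethyl acetate", "ethylacetate", "ethyl-acetate", "etoac", "acoet"),
    "hexane" = c("hexanes", "n-hexane", "hexane"),
    "dichloromethane" = c("dichloromethane", "methylene chloride", "ch2cl2", "dcm"),
    "methanol" = c("methanol", "meoh"),
    "chloroform" = c("chloroform", "chcl3"),
    "petroleum ether" = c("petroleum ether", "petroleumether", "pet. ether", "pet ether", "petrol ether"),
    "diethyl ether" = c("diethyl ether", "diethylether", "ethyl ether", "et2o"),
    "toluene" = c("toluene"),
    "acetone" = c("acetone"),
    "ethanol" = c("ethanol", "etoh")
  )
  tibble::tibble(
    surface = unlist(lex, use.names = FALSE),
    canonical = rep(names(lex), lengths(lex))
  )
}

# Scan one lowercased text for lexicon hits, longest surface form first.
# Matched spans are masked so shorter forms cannot re-match inside them, and
# a hit must not be flanked by a letter/digit (word-boundary rule). Returns
# canonical labels in order of first mention.
scan_solvent_mentions <- function(text, lexicon) {
  lc <- tolower(text)
  n <- nchar(lc)
  mask <- rep(FALSE, n)
  hits <- list()
  lexicon <- lexicon[order(-nchar(lexicon$surface)), ]
  for (i in seq_len(nrow(lexicon))) {
    surf <- lexicon$surface[i]
    m <- gregexpr(surf, lc, fixed = TRUE)[[1]]
    if (m[1] == -1) next
    len <- nchar(surf)
    for (st in as.integer(m)) {
      en <- st + len - 1L
      if (any(mask[st:en])) next
      before <- if (st > 1) substr(lc, st - 1L, st - 1L) else ""
      after <- if (en < n) substr(lc, en + 1L, en + 1L) else ""
      if (grepl("[a-z0-9]", before) || grepl("[a-z0-9]", after)) next
      mask[st:en] <- TRUE
      hits[[length(hits) + 1L]] <- list(canonical = lexicon$canonical[i], pos = st)
    }
  }
  if (length(hits) == 0) return(character(0))
  pos <- vapply(hits, `[[`, numeric(1), "pos")
  canon <- vapply(hits, `[[`, character(1), "canonical")
  first_pos <- vapply(split(pos, canon), min, numeric(1))
  names(sort(first_pos))
}

#' Extract a solvent system from raw purification text
#'
#' Mines a purification paragraph for solvent mentions (via the
#' [solvent_lexicon()]) and the first integer ratio pattern `a:b`. The result
#' carries a status rather than throwing: `ok` (1-2 solvents, usable),
#' `no_solvent`, `too_many_solvents` (3+, too rare to model), or
#' `invalid_ratio` (a ratio was written but is degenerate, e.g. `0:1`, or
#' only a percentage/gradient was given, which the isocratic model does not
#' cover).
#'
#' The raw ratio is read in the textual order of the two solvent mentions and
#' re-oriented so that it always refers to the first label in canonical
#' order: "hexane/ethyl acetate 9:1" stores labels
#' `(ethyl acetate, hexane)` with raw ratio `(1, 9)`.
#'
#' @param text A single purification text.
#' @param lexicon Surface-form lexicon, default [solvent_lexicon()].
#' @return A list with `labels` (canonically ordered character vector),
#'   `raw_ratio` (integer pair oriented to the first canonical label, or
#'   `NULL`), and `status`.
#' @export
#' @examples
#' extract_solvents(
#'   "the residue is chromatographed on silica gel with hexane/ethyl acetate 9:1"
#' )
extract_solvents <- function(text, lexicon = solvent_lexicon()) {
  stopifnot(is.character(text), length(text) == 1)
  mentions <- scan_solvent_mentions(text, lexicon)
  if (length(mentions) == 0) {
    return(list(labels = character(0), raw_ratio = NULL, status = "no_solvent"))
  }
  if (length(mentions) > 2) {
    return(list(labels = mentions, raw_ratio = NULL, status = "too_many_solvents"))
  }
  labels <- canonical_order(mentions)
  if (length(mentions) == 1) {
    return(list(labels = labels, raw_ratio = NULL, status = "ok"))
  }
  m <- regmatches(text, regexpr("([0-9]+)[[:space:]]*:[[:space:]]*([0-9]+)", text))
  if (length(m) == 1) {
    parts <- as.integer(strsplit(gsub("[[:space:]]", "", m), ":")[[1]])
    if (any(parts == 0)) {
      return(list(labels = labels, raw_ratio = NULL, status = "invalid_ratio"))
    }
    # parts follow mention order; swap if canonical ordering swapped the labels
    if (!identical(labels, mentions)) parts <- rev(parts)
    return(list(labels = labels, raw_ratio = parts, status = "ok"))
  }
  if (grepl("[0-9]+[[:space:]]*(%|percent)", tolower(text))) {
    return(list(labels = labels, raw_ratio = NULL, status = "invalid_ratio"))
  }
  list(labels = labels, raw_ratio = NULL, status = "ok")
}

#' Normalize a raw solvent ratio
#'
#' Converts a raw integer ratio `a:b` to the fraction of the first solvent,
#' `a / (a + b)`; the complement `1 - value` is the second solvent's share,
#' so the two normalized values always sum to 1 and only one number needs to
#' be predicted. A ratio of 9:1 normalizes to 0.9.
#'
#' @param a,b Non-negative integer ratio components (vectorized).
#' @return Numeric vector `a / (a + b)`, strictly inside (0, 1).
#' @export
#' @examples
#' normalize_ratio(9, 1) # 0.9
normalize_ratio <- function(a, b) {
  if (any(a < 0) || any(b < 0)) {
    stop("invalid_ratio: negative ratio component")
  }
  if (any(a == 0) || any(b == 0)) {
    stop("invalid_ratio: ratio components must both be positive (0:1 and 0:0 are excluded)")
  }
  a / (a + b)
}

#' Classify extraction results for dataset eligibility
#'
#' Applies the corpus filtering rules to extraction results: records with no
#' solvent or three or more solvents are rejected outright; records whose
#' only flaw is a degenerate written ratio keep their labels (they can still
#' enter the solvent-label dataset) but are not eligible for the ratio
#' dataset.
#'
#' @param results A list of extraction results (as returned by
#'   [extract_solvents()]), or a single result.
#' @return Tibble with one row per result: `status`, `n_labels`,
#'   `ds1_eligible` (labels usable for the classification dataset),
#'   `ds2_eligible` (two solvents with a valid normalizable ratio), `reason`
#'   (`NA` when fully accepted).
#' @export
filter_records <- function(results) {
  if (!is.null(results$status)) results <- list(results)
  tibble::tibble(
    status = vapply(results, `[[`, character(1), "status"),
    n_labels = vapply(results, function(r) length(r$labels), integer(1)),
    has_ratio = vapply(results, function(r) !is.null(r$raw_ratio), logical(1))
  ) |>
    dplyr::mutate(
      ds1_eligible = .data$status %in% c("ok", "invalid_ratio") & .data$n_labels >= 1,
      ds2_eligible = .data$status == "ok" & .data$n_labels == 2 & .data$has_ratio,
      reason = dplyr::if_else(.data$ds1_eligible, NA_character_, .data$status)
    ) |>
    dplyr::select(-"has_ratio")
}

#' Extract solvent systems for a whole record table
#'
#' Data-frame-first wrapper around [extract_solvents()]: runs the lexicon
#' extraction over the `purification_text` column and returns the records
#' augmented with the mined labels, ratio and eligibility flags.
#'
#' @param records Tibble from [reaction_records()] (needs `record_id` and
#'   `purification_text`).
#' @param lexicon Surface-form lexicon.
#' @return The input tibble with added columns `labels` (list), `ratio_a`,
#'   `ratio_b`, `status`, `ds1_eligible`, `ds2_eligible`.
#' @export
extract_purifications <- function(records, lexicon = solvent_lexicon()) {
  res <- purrr::map(records$purification_text, function(tx) {
    if (is.na(tx)) {
      list(labels = character(0), raw_ratio = NULL, status = "no_solvent")
    } else {
      extract_solvents(tx, lexicon)
    }
  })
  flt <- filter_records(res)
  records$labels <- purrr::map(res, "labels")
  records$ratio_a <- vapply(
    res, function(r) if (is.null(r$raw_ratio)) NA_integer_ else r$raw_ratio[1], integer(1)
  )
  records$ratio_b <- vapply(
    res, function(r) if (is.null(r$raw_ratio)) NA_integer_ else r$raw_ratio[2], integer(1)
  )
  records$status <- flt$status
  records$ds1_eligible <- flt$ds1_eligible
  records$ds2_eligible <- flt$ds2_eligible
  records
}
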