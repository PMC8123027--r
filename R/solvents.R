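#' Canonical solvent labels
#'
#' The closed set of ten solvents that normal-phase purification systems are
#' drawn from, ordered by canonical priority. The priority order fixes the
#' orientation of two-solvent systems: the first label of a pair is always the
#' one earlier in this vector, and the mixing ratio always refers to that
#' first label (e.g. "ethyl acetate, hexane" with ratio 0.9 means 90% ethyl
#' acetate). The order is the descending frequency of the labels in the
#' patent-derived corpus, which reproduces the conventional
#' "ethyl acetate / hexane" orientation.
#'
#' @return Character vector of the 10 canonical solvent names, highest
#'   priority first.
#' @export
#' @examples
#' solvent_labels()
solvent_labels <- function() {
  c(
    "ethyl acetate", "hexane", "dichloromethane", "methanol", "chloroform",
    "petroleum ether", "diethyl ether", "toluene", "acetone", "ethanol"
  )
}

#' Order solvent labels canonically
#'
#' Sorts 1-2 solvent labels by the fixed canonical priority list
#' ([solvent_labels()]), so that every solvent system has exactly one
#' representation ("ethyl acetate, hexane" exists; "hexane, ethyl acetate"
#' does not). Idempotent.
#'
#' @param labels Character vector of 1 or 2 canonical solvent names.
#' @return The same labels, ordered by canonical priority.
#' @export
#' @examples
#' canonical_order(c("hexane", "ethyl acetate"))
canonical_order <- function(labels) {
  labels <- unique(labels)
  if (length(labels) < 1 || length(labels) > 2) {
    stop("unsupported solvent system: expected 1-2 labels, got ", length(labels))
  }
  pr <- match(labels, solvent_labels())
  if (anyNA(pr)) {
    stop(
      "unknown solvent label(s): ",
      paste(labels[is.na(pr)], collapse = ", ")
    )
  }
  labels[order(pr)]
}

#' Split a reaction SMILES line into molecules
#'
#' A reaction is written as one line of SMILES with the individual molecules
#' (reactants then products) separated by a "." dot. Whitespace, which
#' sometimes appears inside typeset SMILES, is stripped before splitting.
#'
#' @param line A single reaction SMILES string.
#' @return Character vector of molecule SMILES, in their original order.
#'   Joining the result with "." reproduces the (whitespace-stripped) input.
#' @export
#' @examples
#' split_reaction_smiles("CCO.CC(=O)O")
split_reaction_smiles <- function(line) {
  stopifnot(is.character(line), length(line) == 1)
  line <- gsub("[[:space:]]+", "", line)
  if (!nzchar(line)) stop("malformed record: empty reaction SMILES")
  mols <- strsplit(line, ".", fixed = TRUE)[[1]]
  if (length(mols) == 0 || any(!nzchar(mols))) {
    stop("malformed record: empty molecule fragment between '.' separators")
  }
  mols
}

#' Assemble reaction records
#'
#' Validates a table of raw reaction rows into a tibble of reaction records.
#' Each record is a reaction SMILES of 2-8 dot-separated molecules plus an
#' optional raw purification text. Reactions with more than 8 molecules are
#' dropped with a warning (downstream fingerprint matrices have a fixed 8
#' rows); reactions with fewer than 2 are dropped likewise (a reaction needs
#' at least one reactant and one product).
#'
#' @param data Data frame with columns `record_id`, `reaction_smiles` and
#'   optionally `purification_text` and `n_products` (number of trailing
#'   molecules that are products; default 1).
#' @param max_molecules Upper bound on molecules per reaction (default 8).
#' @return Tibble with columns `record_id`, `reaction_smiles`, `molecules`
#'   (list column), `n_molecules`, `n_products`, `purification_text`.
#' @export
reaction_records <- function(data, max_molecules = 8L) {
  stopifnot(all(c("record_id", "reaction_smiles") %in% names(data)))
  out <- tibble::as_tibble(data[c("record_id", "reaction_smiles")])
  out$purification_text <- if ("purification_text" %in% names(data)) {
    as.character(data$purification_text)
  } else {
    NA_character_
  }
  out$n_products <- if ("n_products" %in% names(data)) {
    as.integer(data$n_products)
  } else {
    1L
  }
  out$reaction_smiles <- gsub("[[:space:]]+", "", out$reaction_smiles)
  out$molecules <- purrr::map(out$reaction_smiles, split_reaction_smiles)
  out$n_molecules <- lengths(out$molecules)
  bad <- out$n_molecules > max_molecules | out$n_molecules < 2L
  if (any(bad)) {
    warning(
      sum(bad), " record(s) dropped: molecule count outside [2, ",
      max_molecules, "]"
    )
    out <- out[!bad, ]
  }
  out[c(
    "record_id", "reaction_smiles", "molecules", "n_molecules",
    "n_products", "purification_text"
  )]
}
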