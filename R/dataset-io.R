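#' Read a solvent-system dataset from a TSV file
#'
#' Datasets are tab-separated UTF-8 files with a header row and columns
#' `id`, `reaction_smiles`, `labels` (comma-separated solvent names, any
#' case), `ratio` (normalized fraction of the first label, empty for
#' single-solvent systems), `split` (`train`/`test`, may be empty before
#' splitting). Labels are canonicalized on read: case-folded, matched
#' against the ten canonical names, and put in canonical priority order.
#'
#' @param path File path.
#' @param task `"DS1"` (solvent labels) or `"DS2"` (two-solvent ratio).
#' @return A dataset tibble with columns `id`, `reaction_smiles`, `labels`
#'   (list column), `ratio`, `split`, and a `task` attribute.
#' @export
read_dataset <- function(path, task = c("DS1", "DS2")) {
  task <- match.arg(task)
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(
      id = readr::col_character(),
      reaction_smiles = readr::col_character(),
      labels = readr::col_character(),
      ratio = readr::col_double(),
      split = readr::col_character()
    ),
    progress = FALSE
  )
  if (nrow(df) == 0) {
    return(new_dataset(tibble::tibble(
      id = character(0), reaction_smiles = character(0),
      labels = list(), ratio = numeric(0), split = character(0)
    ), task))
  }
  labels <- purrr::imap(df$labels, function(s, i) {
    parts <- tolower(trimws(strsplit(s, ",", fixed = TRUE)[[1]]))
    unknown <- setdiff(parts, solvent_labels())
    if (length(unknown) > 0) {
      stop("row ", i, ": unknown solvent name(s): ", paste(unknown, collapse = ", "))
    }
    canonical_order(parts)
  })
  out <- tibble::tibble(
    id = df$id,
    reaction_smiles = gsub("[[:space:]]+", "", df$reaction_smiles),
    labels = labels,
    ratio = df$ratio,
    split = df$split
  )
  if (task == "DS2") {
    bad <- lengths(out$labels) != 2 | is.na(out$ratio) |
      out$ratio <= 0 | out$ratio >= 1
    if (any(bad)) {
      stop(
        "DS2 rows must have exactly 2 labels and a ratio in (0,1); offending row(s): ",
        paste(utils::head(which(bad), 5), collapse = ", ")
      )
    }
  }
  new_dataset(out, task)
}

#' Write a solvent-system dataset to a TSV file
#'
#' Inverse of [read_dataset()]: `read_dataset(write_dataset(ds, f), task)`
#' reproduces `ds` exactly (labels are written in canonical order and
#' canonical spelling).
#'
#' @param dataset Dataset tibble (see [read_dataset()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  df <- tibble::tibble(
    id = dataset$id,
    reaction_smiles = dataset$reaction_smiles,
    labels = vapply(dataset$labels, paste, character(1), collapse = ", "),
    ratio = dataset$ratio,
    split = dataset$split
  )
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Construct a dataset tibble
#'
#' Low-level constructor: attaches the task tag (`"DS1"` solvent labels or
#' `"DS2"` ratio) to an instance tibble with columns `id`,
#' `reaction_smiles`, `labels` (list), `ratio`, `split`.
#'
#' @param df Instance tibble.
#' @param task `"DS1"` or `"DS2"`.
#' @return The tibble with a `task` attribute.
#' @export
new_dataset <- function(df, task) {
  stopifnot(task %in% c("DS1", "DS2"))
  df <- tibble::as_tibble(df)
  attr(df, "task") <- task
  df
}

#' Task tag of a dataset
#'
#' @param dataset Dataset tibble.
#' @return `"DS1"` or `"DS2"`.
#' @export
dataset_task <- function(dataset) {
  task <- attr(dataset, "task", exact = TRUE)
  if (is.null(task)) stop("not a dataset: missing task attribute")
  task
}
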