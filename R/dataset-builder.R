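#' Build the solvent-label dataset (DS1)
#'
#' Assembles the classification dataset from extracted reaction records: one
#' instance per record whose labels passed the corpus filters (one or two
#' solvents; records whose only flaw is a degenerate written ratio keep
#' their labels). Outputs are canonically ordered label sets.
#'
#' @param records Tibble from [extract_purifications()].
#' @return Dataset tibble with task `"DS1"`.
#' @export
build_ds1 <- function(records) {
  keep <- records[records$ds1_eligible, ]
  new_dataset(tibble::tibble(
    id = keep$record_id,
    reaction_smiles = keep$reaction_smiles,
    labels = purrr::map(keep$labels, canonical_order),
    ratio = NA_real_,
    split = NA_character_
  ), "DS1")
}

#' Build the solvent-ratio dataset (DS2)
#'
#' Assembles the regression dataset: only two-solvent records with a valid
#' written ratio enter, and the raw `a:b` ratio is normalized to
#' `a / (a + b)`, the fraction of the first solvent in canonical order. DS2
#' is by construction a subset of DS1's two-solvent instances.
#'
#' @param records Tibble from [extract_purifications()].
#' @return Dataset tibble with task `"DS2"`.
#' @export
build_ds2 <- function(records) {
  keep <- records[records$ds2_eligible, ]
  new_dataset(tibble::tibble(
    id = keep$record_id,
    reaction_smiles = keep$reaction_smiles,
    labels = purrr::map(keep$labels, canonical_order),
    ratio = normalize_ratio(keep$ratio_a, keep$ratio_b),
    split = NA_character_
  ), "DS2")
}

#' Assign a stratified train/test split
#'
#' Reserves `test_fraction` of the instances (nearest-integer total) as the
#' test set, stratified so the test set preserves the distribution of the
#' output space: by label set for DS1, by ratio decile for DS2. Per-stratum
#' test counts are allocated by largest remainder so the overall test size
#' is exactly `round(test_fraction * n)`. Deterministic under a fixed seed.
#'
#' @param dataset Dataset tibble (split column unassigned or ignored).
#' @param test_fraction Fraction held out for testing (default 0.10).
#' @param seed Integer RNG seed.
#' @return The dataset with its `split` column filled with
#'   `"train"`/`"test"`.
#' @export
split_dataset <- function(dataset, test_fraction = 0.10, seed = 1L) {
  n <- nrow(dataset)
  if (n < 10) stop("refusing to split: fewer than 10 instances")
  n_test <- round(test_fraction * n)
  strata <- if (dataset_task(dataset) == "DS1") {
    vapply(dataset$labels, paste, character(1), collapse = " + ")
  } else {
    as.character(pmin(floor(dataset$ratio * 10), 9))
  }
  counts <- table(strata)
  quota <- test_fraction * as.numeric(counts)
  base <- floor(quota)
  rem <- n_test - sum(base)
  if (rem > 0) {
    frac_order <- order(quota - base, decreasing = TRUE)
    base[frac_order[seq_len(rem)]] <- base[frac_order[seq_len(rem)]] + 1
  } else if (rem < 0) {
    elig <- which(base > 0)
    frac_order <- elig[order((quota - base)[elig])]
    base[frac_order[seq_len(-rem)]] <- base[frac_order[seq_len(-rem)]] - 1
  }
  withr::with_seed(seed, {
    split <- rep("train", n)
    for (h in seq_along(counts)) {
      idx <- which(strata == names(counts)[h])
      if (base[h] > 0) {
        take <- if (length(idx) == 1) idx else sample(idx, base[h])
        split[take] <- "test"
      }
    }
    dataset$split <- split
  })
  dataset
}

# Decode a permutation index (factoradic / Lehmer code) into a permutation
# of 1..m. Index 0 is the identity; indices run 0 .. m!-1.
lehmer_permutation <- function(index, m) {
  avail <- seq_len(m)
  perm <- integer(m)
  for (pos in seq_len(m)) {
    f <- factorial(m - pos)
    d <- index %/% f
    index <- index %% f
    perm[pos] <- avail[d + 1L]
    avail <- avail[-(d + 1L)]
  }
  perm
}

#' Augment training instances by permuting molecule order
#'
#' Neural inputs concatenate a reaction's molecules in one arbitrary order,
#' so models must be robust to reorderings. For every *training* instance
#' with `m` molecules this adds `min(cap, m! - 1)` distinct non-identity
#' permutations of the molecule order (labels and ratio unchanged); the test
#' set is never touched, so no augmented twin of a test reaction can leak
#' into training. Permutations are sampled uniformly without replacement
#' under the seed; for a fixed seed, a larger cap extends the sample of a
#' smaller cap (prefix contract), because the full 7-permutation prefix is
#' drawn regardless of the cap.
#'
#' @param dataset Split dataset tibble.
#' @param cap Maximum permutations added per instance, in 2..7 (default 5).
#' @param seed Integer RNG seed.
#' @return The dataset with augmented rows appended; augmented rows carry
#'   `source_id` of their original instance and ids suffixed `#p1`, `#p2`, ...
#' @export
augment_dataset <- function(dataset, cap = 5L, seed = 1L) {
  if (cap < 2 || cap > 7) stop("augmentation cap must be in [2, 7]")
  if (any(is.na(dataset$split))) stop("split must be assigned before augmentation")
  dataset$source_id <- dataset$id
  train_idx <- which(dataset$split == "train")
  withr::with_seed(seed, {
    extra <- purrr::map(train_idx, function(i) {
      mols <- split_reaction_smiles(dataset$reaction_smiles[i])
      m <- length(mols)
      n_nonid <- factorial(m) - 1
      # always draw the maximal 7-prefix so the cap never changes the stream
      prefix <- sample.int(n_nonid, min(7, n_nonid))
      k <- min(cap, n_nonid)
      take <- prefix[seq_len(k)]
      tibble::tibble(
        id = paste0(dataset$id[i], "#p", seq_len(k)),
        reaction_smiles = vapply(take, function(ix) {
          paste(mols[lehmer_permutation(ix, m)], collapse = ".")
        }, character(1)),
        labels = rep(dataset$labels[i], k),
        ratio = dataset$ratio[i],
        split = "train",
        source_id = dataset$source_id[i]
      )
    })
  })
  out <- dplyr::bind_rows(dataset, dplyr::bind_rows(extra))
  new_dataset(out, dataset_task(dataset))
}

#' Classification and regression baselines
#'
#' Computes the no-model reference scores a trained model must beat. For a
#' DS1 dataset the label-*set* distribution (up to 52 combinations) gives
#' the random baseline `sum(p_i^2)` (expected accuracy when predictions are
#' sampled from the empirical distribution) and the majority baseline
#' `max(p_i)` (always predicting the most common set). For a DS2 dataset the
#' constant mean- and median-predictors give the mean-MSE and median-MSE
#' baselines, computed on the test subset (falling back to all instances if
#' the split is unassigned).
#'
#' @param dataset Dataset tibble.
#' @param subset For DS1: which instances the label-set distribution is
#'   estimated from (`"all"`, `"train"` or `"test"`; default all).
#' @return An object of class `eluent_baselines`: a list with either
#'   `random_baseline`, `majority_baseline` and `label_set_distribution`
#'   (DS1) or `mean_mse_baseline` and `median_mse_baseline` (DS2).
#' @export
baselines <- function(dataset, subset = "all") {
  task <- dataset_task(dataset)
  if (nrow(dataset) == 0) stop("empty dataset")
  if (task == "DS1") {
    keep <- if (subset == "all") rep(TRUE, nrow(dataset)) else dataset$split == subset
    if (!any(keep)) stop("empty split: ", subset)
    sets <- vapply(dataset$labels[keep], paste, character(1), collapse = " + ")
    p <- as.numeric(table(sets)) / length(sets)
    dist <- tibble::tibble(
      label_set = names(table(sets)),
      probability = p
    ) |> dplyr::arrange(dplyr::desc(.data$probability))
    structure(list(
      task = task,
      random_baseline = sum(p^2),
      majority_baseline = max(p),
      label_set_distribution = dist
    ), class = "eluent_baselines")
  } else {
    keep <- if (all(is.na(dataset$split))) rep(TRUE, nrow(dataset)) else dataset$split == "test"
    if (!any(keep)) stop("empty test split")
    y <- dataset$ratio[keep]
    structure(list(
      task = task,
      mean_mse_baseline = mean((mean(y) - y)^2),
      median_mse_baseline = mean((stats::median(y) - y)^2),
      n = length(y)
    ), class = "eluent_baselines")
  }
}

#' @export
print.eluent_baselines <- function(x, ...) {
  if (x$task == "DS1") {
    cat("Solvent-system baselines (label sets):\n")
    cat(sprintf("  random baseline   : %.4f\n", x$random_baseline))
    cat(sprintf("  majority baseline : %.4f\n", x$majority_baseline))
    cat(sprintf(
      "  most common set   : %s\n",
      x$label_set_distribution$label_set[1]
    ))
  } else {
    cat("Ratio baselines (constant predictors, test subset):\n")
    cat(sprintf("  mean-MSE baseline   : %.4f\n", x$mean_mse_baseline))
    cat(sprintf("  median-MSE baseline : %.4f\n", x$median_mse_baseline))
  }
  invisible(x)
}
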