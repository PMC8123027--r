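make_records <- function() {
  extract_purifications(reaction_records(tibble::tibble(
    record_id = c("r1", "r2", "r3"),
    reaction_smiles = c("CCO.CC", "CCN.CC", "CCO.CCN"),
    purification_text = c(
      "chromatographed with methanol",
      "chromatographed with toluene",
      "chromatographed with ethyl acetate/hexane 2:3"
    )
  )))
}

test_that("DS1 and DS2 assemble from filtered records", {
  rec <- make_records()
  ds1 <- build_ds1(rec)
  ds2 <- build_ds2(rec)
  expect_equal(nrow(ds1), 3)
  expect_equal(nrow(ds2), 1)
  expect_equal(ds2$ratio, 0.4) # 2:3 normalized
  expect_identical(dataset_task(ds1), "DS1")
  expect_identical(dataset_task(ds2), "DS2")
  # DS2 is the two-solvent subset of DS1
  expect_true(all(ds2$id %in% ds1$id[lengths(ds1$labels) == 2]))
})

test_that("records with degenerate ratios stay in DS1 but not DS2", {
  rec <- extract_purifications(reaction_records(tibble::tibble(
    record_id = "x",
    reaction_smiles = "CCO.CC",
    purification_text = "with ethyl acetate/hexane 0:1"
  )))
  expect_equal(nrow(build_ds1(rec)), 1)
  expect_equal(nrow(build_ds2(rec)), 0)
})

test_that("the split reserves round(0.1 n) test instances, stratified", {
  syn <- synth_small()
  ds1 <- split_dataset(syn$ds1, 0.10, seed = 9)
  expect_equal(sum(ds1$split == "test"), round(0.1 * nrow(ds1)))
  expect_equal(sum(ds1$split == "train"), nrow(ds1) - round(0.1 * nrow(ds1)))
  # stratification: each common label set is represented near 10% in test
  sets <- vapply(ds1$labels, paste, character(1), collapse = "+")
  for (s in names(which(table(sets) >= 50))) {
    frac <- mean(ds1$split[sets == s] == "test")
    expect_gt(frac, 0.05)
    expect_lt(frac, 0.15)
  }
  # deterministic under the seed
  again <- split_dataset(syn$ds1, 0.10, seed = 9)
  expect_identical(ds1$split, again$split)
  other <- split_dataset(syn$ds1, 0.10, seed = 10)
  expect_false(identical(ds1$split, other$split))
})

test_that("a ten-instance dataset yields exactly one test instance", {
  ds <- new_dataset(tibble::tibble(
    id = sprintf("r%d", 1:10),
    reaction_smiles = rep("CCO.CC", 10),
    labels = rep(list("methanol"), 10),
    ratio = NA_real_, split = NA_character_
  ), "DS1")
  out <- split_dataset(ds, 0.10, seed = 1)
  expect_equal(sum(out$split == "test"), 1)
  expect_error(split_dataset(out[1:9, ], 0.10, seed = 1), "fewer than 10")
})

test_that("augmentation adds min(cap, m!-1) distinct non-identity orders", {
  base <- function(smiles) {
    ds <- new_dataset(tibble::tibble(
      id = "a", reaction_smiles = smiles,
      labels = list("methanol"), ratio = NA_real_, split = "train"
    ), "DS1")
    ds
  }
  # m = 2: only one non-identity permutation exists
  out2 <- augment_dataset(base("CCO.CC"), cap = 5, seed = 1)
  expect_equal(nrow(out2), 2)
  expect_identical(out2$reaction_smiles[2], "CC.CCO")

  # m = 3: all 3! - 1 = 5 non-identity permutations, verified by enumeration
  mols3 <- c("CCO", "CC", "CCN")
  out3 <- augment_dataset(base(paste(mols3, collapse = ".")), cap = 5, seed = 1)
  added <- out3$reaction_smiles[-1]
  all_perms <- vapply(
    enumerate_permutations(3),
    function(p) paste(mols3[p], collapse = "."), character(1)
  )
  non_identity <- setdiff(all_perms, paste(mols3, collapse = "."))
  expect_setequal(added, non_identity)

  # m = 4, cap 5: five distinct non-identity orders out of the 23 possible
  mols4 <- c("CCO", "CC", "CCN", "CCCl")
  out4 <- augment_dataset(base(paste(mols4, collapse = ".")), cap = 5, seed = 1)
  added4 <- out4$reaction_smiles[-1]
  expect_length(added4, 5)
  expect_length(unique(added4), 5)
  all4 <- vapply(
    enumerate_permutations(4),
    function(p) paste(mols4[p], collapse = "."), character(1)
  )
  expect_true(all(added4 %in% setdiff(all4, paste(mols4, collapse = "."))))
})

test_that("augmentation leaves the test split untouched and never leaks", {
  syn <- synth_small()
  ds <- split_dataset(syn$ds1, 0.10, seed = 4)
  aug <- augment_dataset(ds, cap = 3, seed = 4)
  expect_equal(
    sum(aug$split == "test"), sum(ds$split == "test")
  )
  # every augmented row's source record lives in exactly one split
  split_of <- tapply(aug$split, aug$source_id, function(s) length(unique(s)))
  expect_true(all(split_of == 1))
  # outputs unchanged
  first_aug <- aug[aug$id == paste0(aug$source_id, "#p1"), ]
  orig <- ds[match(first_aug$source_id, ds$id), ]
  expect_identical(first_aug$labels, orig$labels)
})

test_that("a larger cap extends a smaller cap's sample under one seed", {
  syn <- synth_small()
  ds <- split_dataset(syn$ds1, 0.10, seed = 5)
  small <- augment_dataset(ds, cap = 3, seed = 77)
  big <- augment_dataset(ds, cap = 6, seed = 77)
  expect_true(all(small$id %in% big$id))
  sm <- small[grepl("#p", small$id), ]
  bg <- big[match(sm$id, big$id), ]
  expect_identical(sm$reaction_smiles, bg$reaction_smiles)
  expect_error(augment_dataset(ds, cap = 1, seed = 1), "cap")
  expect_error(augment_dataset(ds, cap = 8, seed = 1), "cap")
})

test_that("classification baselines match the closed-form toy values", {
  mk <- function(sets) {
    new_dataset(tibble::tibble(
      id = sprintf("r%d", seq_along(sets)),
      reaction_smiles = rep("CCO.CC", length(sets)),
      labels = sets, ratio = NA_real_, split = NA_character_
    ), "DS1")
  }
  b <- baselines(mk(c(rep(list("methanol"), 5), rep(list("toluene"), 5))))
  expect_equal(b$random_baseline, 0.5)
  expect_equal(b$majority_baseline, 0.5)

  sets <- c(
    rep(list(c("ethyl acetate", "hexane")), 7),
    rep(list("methanol"), 2),
    rep(list("toluene"), 1)
  )
  b2 <- baselines(mk(sets))
  expect_equal(b2$random_baseline, 0.49 + 0.04 + 0.01)
  expect_equal(b2$majority_baseline, 0.7)
  expect_identical(
    b2$label_set_distribution$label_set[1], "ethyl acetate + hexane"
  )
  expect_named(
    glance(b2), c("random_baseline", "majority_baseline", "n_label_sets")
  )
  expect_s3_class(autoplot(b2), "ggplot")
})

test_that("regression baselines are constant-predictor MSEs on the test set", {
  ds <- new_dataset(tibble::tibble(
    id = c("a", "b"), reaction_smiles = rep("CCO.CC", 2),
    labels = rep(list(c("ethyl acetate", "hexane")), 2),
    ratio = c(0.001, 0.998), split = c("test", "test")
  ), "DS2")
  ds$ratio <- c(0, 1) # boundary case for the arithmetic check
  b <- baselines(ds)
  expect_equal(b$mean_mse_baseline, 0.25)
  expect_equal(b$median_mse_baseline, 0.25)
})

test_that("baseline formulas agree with brute-force oracles at random", {
  set.seed(123)
  for (i in 1:60) {
    k <- sample(2:8, 1)
    counts <- as.vector(stats::rmultinom(1, size = sample(20:200, 1), prob = rep(1, k)))
    counts <- counts[counts > 0]
    p <- counts / sum(counts)
    # oracle: direct summation over the distribution
    expect_equal(sum(p^2), sum(vapply(p, function(x) x * x, numeric(1))))
    sets <- unlist(purrr::map2(
      sprintf("s%d", seq_along(counts)), counts, rep
    ))
    ds <- new_dataset(tibble::tibble(
      id = sprintf("r%d", seq_along(sets)),
      reaction_smiles = "CCO.CC",
      labels = purrr::map(sets, function(s) solvent_labels()[as.integer(sub("s", "", s))]),
      ratio = NA_real_, split = NA_character_
    ), "DS1")
    b <- baselines(ds)
    expect_equal(b$random_baseline, sum(p^2))
    expect_equal(b$majority_baseline, max(p))
    expect_gte(b$random_baseline, 1 / length(p))
    expect_gte(b$majority_baseline, max(p) - 1e-12)
  }
  # mean-MSE equals the biased variance of the test ratios
  for (i in 1:20) {
    y <- stats::runif(sample(5:50, 1))
    ds <- new_dataset(tibble::tibble(
      id = sprintf("r%d", seq_along(y)), reaction_smiles = "CCO.CC",
      labels = rep(list(c("ethyl acetate", "hexane")), length(y)),
      ratio = y, split = "test"
    ), "DS2")
    b <- baselines(ds)
    expect_equal(b$mean_mse_baseline, mean((y - mean(y))^2))
    expect_gte(b$median_mse_baseline, 0)
  }
})
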