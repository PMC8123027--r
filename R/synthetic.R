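#' Planted functional-group rules for synthetic reactions
#'
#' The synthetic generator rests on the premise the real task rests on:
#' the functional groups of a reaction's molecules determine the
#' purification solvent system. Each rule maps a SMARTS trigger to a
#' solvent system; rules are checked in priority order and the first
#' triggered rule assigns the labels. For two-solvent rules the normalized
#' ratio follows a linear law in the total trigger count across the
#' reaction's molecules, `ratio = base + increment * count`, plus Gaussian
#' noise — so the labels are an exact function of molecular substructure
#' and the ratio is recoverable up to the noise floor.
#'
#' @return Tibble with columns `rule_id`, `priority`, `trigger` (SMARTS,
#'   `NA` for the fallback), `group` (decorating-group SMILES prefix that
#'   plants the trigger), `labels` (list, canonical order), `base`,
#'   `increment` (ratio law; `NA` for single-solvent systems), `weight`
#'   (sampling weight shaping the class imbalance).
#' @export
planted_rules <- function() {
  tibble::tibble(
    rule_id = c("carboxyl", "amine", "hydroxyl", "nitrile", "plain"),
    priority = 1:5,
    trigger = c("[CX3](=O)[OX2H1]", "[NX3;H2]", "[OX2H]", "C#N", NA),
    group = c("OC(=O)", "N", "O", "N#C", NA),
    labels = list(
      c("dichloromethane", "methanol"),
      c("methanol", "chloroform"),
      c("ethyl acetate", "hexane"),
      "dichloromethane",
      "ethyl acetate"
    ),
    base = c(0.60, 0.50, 0.30, NA, NA),
    increment = c(0.05, 0.05, 0.10, NA, NA),
    weight = c(0.20, 0.15, 0.50, 0.08, 0.07)
  )
}

#' Synthetic molecule pool
#'
#' Builds ~200 small molecules as scaffold x decorating-group combinations
#' (a SMILES prefix bonded onto the scaffold's first atom). Five groups
#' plant rule triggers (hydroxyl, carboxyl, primary amine, nitrile) and
#' the rest are neutral decorations, so extended-connectivity fingerprint
#' bits cleanly separate the planted rules while scaffolds provide
#' structural variety.
#'
#' @return Tibble with `smiles`, `scaffold`, `group`, and one count column
#'   per SMARTS trigger of [planted_rules()].
#' @export
synthetic_pool <- function() {
  key <- "synthetic_pool"
  if (exists(key, envir = .eluent_cache)) {
    return(get(key, envir = .eluent_cache))
  }
  scaffolds <- c(
    "c1ccccc1", "c1ccc(C)cc1", "c1ccc(F)cc1", "c1ccc(OC)cc1", "c1ccc(Cl)cc1",
    "c1ccc2ccccc2c1", "c1ccsc1", "c1ccco1", "Cc1ccccc1", "CCc1ccccc1",
    "C=Cc1ccccc1", "Cc1ccco1", "C1CCCCC1", "C1CCCC1", "CC1CCCCC1",
    "C1CCOC1", "C1CCNCC1", "CCCC", "CCCCCC", "CC(C)C"
  )
  groups <- c(
    "O", "OC(=O)", "N", "N#C", "Cl",
    "C", "CC", "CO", "FC(F)(F)", "CN(C)"
  )
  pool <- tidyr::expand_grid(group = groups, scaffold = scaffolds)
  pool$smiles <- paste0(pool$group, pool$scaffold)
  # validate through the SMILES parser (throws on anything malformed)
  pool$smiles <- unname(canonical_smiles(pool$smiles))
  rules <- planted_rules()
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(pool$smiles))
  ChemmineR::cid(sdf) <- as.character(seq_len(nrow(pool)))
  for (r in which(!is.na(rules$trigger))) {
    pool[[paste0("n_", rules$rule_id[r])]] <-
      as.integer(ChemmineR::smartsSearchOB(sdf, rules$trigger[r], uniqueMatches = TRUE))
  }
  attr(pool, "triggers") <- rules$trigger[!is.na(rules$trigger)]
  assign(key, pool, envir = .eluent_cache)
  pool
}

#' Synthetic dataset configuration
#'
#' @param n_reactions Number of reactions to generate (>= 100 for training
#'   uses; smaller values are allowed for unit tests).
#' @param seed Integer seed; generation is fully reproducible per seed.
#' @param ratio_noise_sd Gaussian noise on the ratio law (default 0.02).
#' @param rules Planted rule set (default [planted_rules()]).
#' @param ratio_denominator Grid for the written a:b ratio in the rendered
#'   purification text (default 20, i.e. 0.05 steps).
#' @return Config list of class `eluent_synth_config`.
#' @export
synthetic_config <- function(n_reactions = 1000L, seed = 1L,
                             ratio_noise_sd = 0.02, rules = planted_rules(),
                             ratio_denominator = 20L) {
  stopifnot(n_reactions >= 1, ratio_noise_sd >= 0)
  structure(list(
    n_reactions = as.integer(n_reactions), seed = as.integer(seed),
    ratio_noise_sd = ratio_noise_sd, rules = rules,
    ratio_denominator = as.integer(ratio_denominator)
  ), class = "eluent_synth_config")
}

# render templates modelled on raw patent purification phrasings
render_templates <- function() {
  list(
    two = c(
      "the residue is chromatographed on silica gel with %s/%s %d:%d",
      "the residue was purified by column chromatography on silicagel with %s/%s (%d:%d)",
      "the residue was chromatographed rapidly on silica gel 60 eluting with %s/%s (%d:%d parts by volume)"
    ),
    one = c(
      "the residue is chromatographed on silica gel with %s",
      "the crude product was purified by column chromatography eluting with %s"
    )
  )
}

render_surfaces <- function() {
  list(
    "ethyl acetate" = c("ethyl acetate", "ethylacetate"),
    "hexane" = c("hexane", "hexanes"),
    "dichloromethane" = c("dichloromethane", "methylene chloride"),
    "methanol" = c("methanol", "MeOH"),
    "chloroform" = c("chloroform"),
    "petroleum ether" = c("petroleum ether"),
    "diethyl ether" = c("diethyl ether"),
    "toluene" = c("toluene"),
    "acetone" = c("acetone"),
    "ethanol" = c("ethanol")
  )
}

#' Render a purification text for a solvent system
#'
#' Produces a raw-text purification sentence (templated on patent
#' phrasings) from which the extraction module recovers exactly the input
#' system and raw ratio (round-trip property). For two-solvent systems the
#' solvents may be printed in either order; the written `a:b` ratio always
#' follows the printed order, as in real text.
#'
#' @param labels Canonical 1-2 solvent labels.
#' @param raw_ratio Integer pair (fraction of the first canonical label),
#'   required for two-solvent systems.
#' @param template Template index (1-3 for pairs, 1-2 for singles).
#' @param swap Print the pair in reverse canonical order.
#' @param surfaces Index used to pick a surface form per label (1 = first).
#' @return A single character string.
#' @export
render_purification_text <- function(labels, raw_ratio = NULL, template = 1L,
                                     swap = FALSE, surfaces = 1L) {
  sf <- render_surfaces()
  pick <- function(lab, i) {
    forms <- sf[[lab]]
    forms[(i - 1L) %% length(forms) + 1L]
  }
  tpl <- render_templates()
  if (length(labels) == 2) {
    stopifnot(!is.null(raw_ratio), length(raw_ratio) == 2)
    a <- labels[1]; b <- labels[2]; r <- raw_ratio
    if (swap) {
      a <- labels[2]; b <- labels[1]; r <- rev(raw_ratio)
    }
    sprintf(
      tpl$two[(template - 1L) %% length(tpl$two) + 1L],
      pick(a, surfaces), pick(b, surfaces), r[1], r[2]
    )
  } else {
    sprintf(
      tpl$one[(template - 1L) %% length(tpl$one) + 1L],
      pick(labels[1], surfaces)
    )
  }
}

#' Generate a synthetic reaction corpus with planted structure
#'
#' Emits desk-scale reaction records whose solvent systems follow the
#' planted functional-group rules: a reaction of 2-8 pool molecules is
#' assembled around a sampled rule (its trigger group present in 1-4
#' reactant molecules and in the product, no higher-priority trigger
#' anywhere), the labels come from the highest-priority triggered rule,
#' and the two-solvent ratio follows the rule's linear law in the total
#' SMARTS trigger count plus Gaussian noise, clipped inside (0.02, 0.98).
#' Every record also carries a rendered purification text (see
#' [render_purification_text()]) whose written integer ratio is the
#' ratio-law value on a 1/`ratio_denominator` grid, so the extraction
#' module can be exercised end to end.
#'
#' @param config An [synthetic_config()].
#' @return List with `records` (tibble: `record_id`, `reaction_smiles`,
#'   `n_products`, `purification_text`, `ratio_a`, `ratio_b`), `ds1` and
#'   `ds2` (ground-truth datasets, unsplit), and `truth` (tibble with the
#'   assigned `rule_id` and trigger `count` per record).
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  pool <- synthetic_pool()
  rules <- config$rules[order(config$rules$priority), ]
  trig_rules <- rules[!is.na(rules$trigger), ]
  count_cols <- paste0("n_", trig_rules$rule_id)
  cached_triggers <- attr(pool, "triggers", exact = TRUE)
  if (length(setdiff(count_cols, names(pool))) > 0 ||
    !identical(cached_triggers, trig_rules$trigger)) {
    pool <- synthetic_pool_counts(pool, trig_rules)
  }
  # molecules that trigger nothing at all
  neutral_idx <- which(rowSums(pool[count_cols]) == 0)
  if (length(neutral_idx) == 0) stop("rule set leaves no neutral pool molecule")
  rule_mols <- lapply(seq_len(nrow(trig_rules)), function(r) {
    ok <- pool[[count_cols[r]]] > 0
    if (r > 1) {
      for (hc in count_cols[seq_len(r - 1)]) ok <- ok & pool[[hc]] == 0
    }
    which(ok)
  })
  names(rule_mols) <- trig_rules$rule_id
  empty <- lengths(rule_mols) == 0
  if (any(empty)) {
    stop(
      "rule(s) covering no pool molecule: ",
      paste(trig_rules$rule_id[empty], collapse = ", ")
    )
  }
  n <- config$n_reactions
  q <- config$ratio_denominator
  withr::with_seed(config$seed, {
    rule_pick <- sample(rules$rule_id, n, replace = TRUE, prob = rules$weight)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      rid <- rule_pick[i]
      r <- match(rid, rules$rule_id)
      n_mol <- sample(2:8, 1, prob = c(1, 2, 3, 3, 2, 1, 1))
      n_react <- n_mol - 1L
      if (is.na(rules$trigger[r])) {
        mols_idx <- sample(neutral_idx, n_react, replace = TRUE)
        prod_idx <- sample(neutral_idx, 1)
        count <- 0L
      } else {
        k_trig <- sample(seq_len(min(4, n_react)), 1)
        cand <- rule_mols[[rid]]
        trig <- sample(cand, k_trig, replace = TRUE)
        neut <- if (n_react - k_trig > 0) {
          sample(neutral_idx, n_react - k_trig, replace = TRUE)
        } else {
          integer(0)
        }
        mols_idx <- c(trig, neut)
        mols_idx <- mols_idx[sample.int(length(mols_idx))] # shuffle order
        # product keeps the rule's functional group on a different scaffold
        prod_idx <- sample(cand, 1)
        count <- sum(pool[[count_cols[match(rid, trig_rules$rule_id)]]][c(mols_idx, prod_idx)])
      }
      labels <- canonical_order(rules$labels[[r]])
      two <- length(labels) == 2
      ratio <- NA_real_
      ratio_a <- NA_integer_; ratio_b <- NA_integer_
      if (two) {
        law <- min(max(rules$base[r] + rules$increment[r] * count, 0.05), 0.95)
        ratio <- min(max(law + stats::rnorm(1, 0, config$ratio_noise_sd), 0.02), 0.98)
        a <- min(max(round(q * ratio), 1L), q - 1L)
        g <- gcd_int(a, q - a)
        ratio_a <- as.integer(a / g); ratio_b <- as.integer((q - a) / g)
      }
      text <- render_purification_text(
        labels,
        raw_ratio = if (two) c(ratio_a, ratio_b) else NULL,
        template = sample(3L, 1),
        swap = two && stats::runif(1) < 0.5,
        surfaces = sample(2L, 1)
      )
      rows[[i]] <- tibble::tibble(
        record_id = sprintf("synth-%05d", i),
        reaction_smiles = paste(pool$smiles[c(mols_idx, prod_idx)], collapse = "."),
        n_products = 1L,
        purification_text = text,
        labels = list(labels),
        ratio = ratio,
        ratio_a = ratio_a,
        ratio_b = ratio_b,
        rule_id = rid,
        count = count
      )
    }
  })
  all <- dplyr::bind_rows(rows)
  ds1 <- new_dataset(tibble::tibble(
    id = all$record_id, reaction_smiles = all$reaction_smiles,
    labels = all$labels, ratio = NA_real_, split = NA_character_
  ), "DS1")
  two <- lengths(all$labels) == 2
  ds2 <- new_dataset(tibble::tibble(
    id = all$record_id[two], reaction_smiles = all$reaction_smiles[two],
    labels = all$labels[two], ratio = all$ratio[two], split = NA_character_
  ), "DS2")
  list(
    records = all[c(
      "record_id", "reaction_smiles", "n_products", "purification_text",
      "ratio_a", "ratio_b"
    )],
    ds1 = ds1,
    ds2 = ds2,
    truth = all[c("record_id", "rule_id", "labels", "ratio", "count")]
  )
}

gcd_int <- function(a, b) {
  while (b != 0) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

# recompute trigger-count columns for a custom rule set
synthetic_pool_counts <- function(pool, trig_rules) {
  pool <- pool[c("group", "scaffold", "smiles")]
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(pool$smiles))
  ChemmineR::cid(sdf) <- as.character(seq_len(nrow(pool)))
  for (r in seq_len(nrow(trig_rules))) {
    pool[[paste0("n_", trig_rules$rule_id[r])]] <-
      as.integer(ChemmineR::smartsSearchOB(sdf, trig_rules$trigger[r], uniqueMatches = TRUE))
  }
  attr(pool, "triggers") <- trig_rules$trigger
  pool
}
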