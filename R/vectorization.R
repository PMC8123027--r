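#' Build a character vocabulary from reaction SMILES
#'
#' Character-level tokenization: every distinct character observed in the
#' training corpus (including the "." molecule separator) becomes one
#' symbol. Two indices are reserved: `PAD` (0) for right-padding and `UNK`
#' (1) for characters never seen at build time; observed characters get
#' dense indices from 2 in first-seen order. On the full patent corpus this
#' yields on the order of 56 symbols.
#'
#' @param corpus Character vector of reaction SMILES strings.
#' @return A list with `symbols` (named integer vector, 0-based indices),
#'   `size` (total vocabulary size incl. PAD/UNK), `pad` and `unk` indices.
#' @export
build_vocabulary <- function(corpus) {
  stopifnot(length(corpus) > 0)
  chars <- unique(unlist(strsplit(paste(corpus, collapse = ""), "", fixed = TRUE)))
  idx <- seq_along(chars) + 1L
  names(idx) <- chars
  list(
    symbols = c(c("<PAD>" = 0L, "<UNK>" = 1L), idx),
    size = length(chars) + 2L,
    pad = 0L,
    unk = 1L
  )
}

#' Tokenize reaction SMILES into fixed-length index sequences
#'
#' Maps each character of a reaction string to its vocabulary index,
#' right-pads with `PAD` to `max_len` and truncates longer inputs at
#' `max_len` (with a warning); unseen characters map to `UNK`. The fixed
#' length of 200 keeps the full input of essentially all reactions while
#' giving the downstream embedding a constant 200-row matrix.
#'
#' @param reactions Character vector of reaction SMILES.
#' @param vocab Vocabulary from [build_vocabulary()].
#' @param max_len Sequence length (default 200).
#' @return Integer matrix, one row per reaction, `max_len` columns, 0-based
#'   indices.
#' @export
tokenize <- function(reactions, vocab, max_len = 200L) {
  out <- matrix(vocab$pad, nrow = length(reactions), ncol = max_len)
  truncated <- 0L
  for (i in seq_along(reactions)) {
    ch <- strsplit(reactions[i], "", fixed = TRUE)[[1]]
    if (length(ch) > max_len) {
      truncated <- truncated + 1L
      ch <- ch[seq_len(max_len)]
    }
    ix <- vocab$symbols[ch]
    ix[is.na(ix)] <- vocab$unk
    if (length(ch) > 0) out[i, seq_along(ch)] <- ix
  }
  if (truncated > 0) {
    warning(truncated, " sequence(s) longer than ", max_len, " truncated")
  }
  out
}

# --- molecular graphs ------------------------------------------------------

# cache: canonical SMILES and fingerprints, keyed per session
.eluent_cache <- new.env(parent = emptyenv())

#' Clear the molecule/fingerprint cache
#' @return Invisibly, NULL.
#' @export
clear_fingerprint_cache <- function() {
  rm(list = ls(.eluent_cache), envir = .eluent_cache)
  invisible(NULL)
}

# Canonicalize SMILES through OpenBabel so that any atom numbering or
# Kekule/aromatic writing of the same molecule maps to one string.
canonical_smiles <- function(smiles) {
  key <- paste0("can:", smiles)
  hit <- vapply(key, function(k) exists(k, envir = .eluent_cache), logical(1))
  if (any(!hit)) {
    todo <- smiles[!hit]
    res <- ChemmineOB::convertFormat("SMI", "CAN", paste(todo, collapse = "\n"))
    can <- strsplit(res, "\n", fixed = TRUE)[[1]]
    can <- sub("[[:space:]]+$", "", can)
    if (length(can) != length(todo) || any(!nzchar(can))) {
      bad <- if (length(can) == length(todo)) todo[!nzchar(can)] else todo
      stop("unparsable SMILES: ", paste(utils::head(bad, 3), collapse = ", "))
    }
    for (j in seq_along(todo)) {
      assign(paste0("can:", todo[j]), can[j], envir = .eluent_cache)
    }
  }
  vapply(smiles, function(s) get(paste0("can:", s), envir = .eluent_cache), character(1))
}

# Extract element symbols and bond lists for a batch of canonical SMILES.
# OpenBabel emits standard V2000 molfiles; the fixed-width counts/atom/bond
# blocks are parsed directly (SDF readers in the environment drop valid
# zero-bond molecules such as bare metal atoms).
molecule_graphs <- function(can_smiles) {
  sdf <- ChemmineOB::convertFormat("SMI", "SDF", paste(can_smiles, collapse = "\n"))
  blocks <- strsplit(sdf, "\\${4}\n?")[[1]]
  blocks <- blocks[grepl("V2000", blocks)]
  if (length(blocks) != length(can_smiles)) {
    stop("unparsable SMILES in batch (got ", length(blocks), " molfiles for ",
         length(can_smiles), " inputs)")
  }
  purrr::map2(blocks, can_smiles, function(bl, smi) {
    lines <- strsplit(bl, "\n", fixed = TRUE)[[1]]
    counts_at <- grep("V2000", lines)[1]
    n_atoms <- as.integer(substr(lines[counts_at], 1, 3))
    n_bonds <- as.integer(substr(lines[counts_at], 4, 6))
    if (is.na(n_atoms) || n_atoms == 0) stop("unparsable SMILES (no atoms): ", smi)
    atom_lines <- lines[counts_at + seq_len(n_atoms)]
    elements <- trimws(substr(atom_lines, 32, 34))
    bonds <- if (n_bonds == 0) {
      matrix(integer(0), ncol = 3)
    } else {
      bl2 <- lines[counts_at + n_atoms + seq_len(n_bonds)]
      cbind(
        as.integer(substr(bl2, 1, 3)),
        as.integer(substr(bl2, 4, 6)),
        as.integer(substr(bl2, 7, 9))
      )
    }
    list(elements = elements, bonds = bonds)
  })
}

# Deterministic rolling hash of an integer vector into [0, 2^31 - 2].
# Exact in double arithmetic: intermediate values stay far below 2^53.
hash_ints <- function(v) {
  h <- 5381
  for (x in v) h <- (h * 33 + x) %% 2147483647
  h
}

#' Extended-connectivity fingerprints
#'
#' Hashes each molecule's circular atom neighborhoods into a fixed-length
#' binary vector (the Morgan/ECFP scheme). Initial atom codes combine the
#' element, heavy-atom degree and total bond order; `radius` rounds of
#' neighborhood refinement then fold in increasingly wide substructure
#' environments, and every (atom, round) identifier sets one bit (modulo
#' `n_bits`). Molecules are canonicalized through OpenBabel first, so two
#' SMILES writings of the same molecular graph (atom renumbering,
#' aromatic vs. Kekule) produce identical fingerprints.
#'
#' @param smiles Character vector of single-molecule SMILES.
#' @param n_bits Fingerprint length in bits (default 512).
#' @param radius Neighborhood radius in bonds (default 2, the ECFP4
#'   convention).
#' @return Binary integer matrix, `length(smiles)` rows by `n_bits` columns.
#' @export
#' @examples
#' \donttest{
#' f <- ecfp(c("c1ccccc1", "C1=CC=CC=C1"))
#' identical(f[1, ], f[2, ]) # TRUE: same molecule, different writing
#' }
ecfp <- function(smiles, n_bits = 512L, radius = 2L) {
  stopifnot(n_bits >= 8, radius >= 0)
  can <- canonical_smiles(smiles)
  out <- matrix(0L, nrow = length(smiles), ncol = n_bits)
  keys <- paste0("fp:", n_bits, ":", radius, ":", can)
  todo <- !duplicated(can) &
    !vapply(keys, function(k) exists(k, envir = .eluent_cache), logical(1))
  graphs <- if (any(todo)) molecule_graphs(can[todo]) else list()
  names(graphs) <- can[todo]
  for (i in seq_along(can)) {
    key <- keys[i]
    if (!exists(key, envir = .eluent_cache)) {
      g <- graphs[[can[i]]]
      n_atoms <- length(g$elements)
      nbr <- vector("list", n_atoms)
      if (nrow(g$bonds) > 0) {
        for (b in seq_len(nrow(g$bonds))) {
          a1 <- g$bonds[b, 1]; a2 <- g$bonds[b, 2]; o <- g$bonds[b, 3]
          nbr[[a1]] <- rbind(nbr[[a1]], c(a2, o))
          nbr[[a2]] <- rbind(nbr[[a2]], c(a1, o))
        }
      }
      elem_code <- vapply(g$elements, function(e) sum(utf8ToInt(e) * seq_along(utf8ToInt(e))), numeric(1))
      degree <- vapply(nbr, function(x) if (is.null(x)) 0L else nrow(x), integer(1))
      bondsum <- vapply(nbr, function(x) if (is.null(x)) 0 else sum(x[, 2]), numeric(1))
      inv <- vapply(seq_len(n_atoms), function(a) {
        hash_ints(c(elem_code[a], degree[a], bondsum[a]))
      }, numeric(1))
      feats <- inv
      for (r in seq_len(radius)) {
        inv <- vapply(seq_len(n_atoms), function(a) {
          if (is.null(nbr[[a]])) return(hash_ints(c(r, inv[a])))
          pairs <- cbind(nbr[[a]][, 2], inv[nbr[[a]][, 1]])
          pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
          hash_ints(c(r, inv[a], as.vector(t(pairs))))
        }, numeric(1))
        feats <- c(feats, inv)
      }
      bits <- unique(as.integer(feats %% n_bits)) + 1L
      assign(key, bits, envir = .eluent_cache)
    }
    out[i, get(key, envir = .eluent_cache)] <- 1L
  }
  rownames(out) <- NULL
  out
}

#' Reaction fingerprint matrix
#'
#' Stacks the per-molecule ECFPs of one reaction into a fixed 8 x `n_bits`
#' matrix: row i is molecule i (so permuting the molecule order permutes the
#' rows), and rows beyond the molecule count are all zero. With
#' `products_only = TRUE` only the product molecules are used and their
#' fingerprints are OR-combined into a single 1 x `n_bits` row (the
#' products-only input variant).
#'
#' @param reaction_smiles A single reaction SMILES (molecules joined by ".").
#' @param n_bits,radius Fingerprint parameters (see [ecfp()]).
#' @param products_only Use only the product molecules, collapsed to one row.
#' @param n_products Number of trailing molecules that are products
#'   (default 1).
#' @param max_molecules Fixed row count of the matrix (default 8).
#' @return Binary integer matrix: 8 x `n_bits`, or 1 x `n_bits` when
#'   `products_only`.
#' @export
reaction_fingerprint <- function(reaction_smiles, n_bits = 512L, radius = 2L,
                                 products_only = FALSE, n_products = 1L,
                                 max_molecules = 8L) {
  mols <- split_reaction_smiles(reaction_smiles)
  if (length(mols) > max_molecules) {
    stop("reaction has ", length(mols), " molecules; maximum is ", max_molecules)
  }
  if (products_only) {
    prod <- mols[seq.int(length(mols) - n_products + 1L, length(mols))]
    fp <- ecfp(prod, n_bits = n_bits, radius = radius)
    return(matrix(as.integer(colSums(fp) > 0), nrow = 1))
  }
  out <- matrix(0L, nrow = max_molecules, ncol = n_bits)
  out[seq_along(mols), ] <- ecfp(mols, n_bits = n_bits, radius = radius)
  out
}

#' Flatten a reaction fingerprint matrix
#'
#' Row-major flattening of the 8 x 512 matrix into a 1 x 4096 vector
#' (molecule 1's bits first). Reversible via [unflatten_fingerprint()].
#'
#' @param fp_matrix Matrix from [reaction_fingerprint()].
#' @return Integer vector of length `nrow * ncol`.
#' @export
flatten_fingerprint <- function(fp_matrix) {
  as.integer(t(fp_matrix))
}

#' @rdname flatten_fingerprint
#' @param flat Flattened vector.
#' @param n_bits Number of columns of the original matrix.
#' @export
unflatten_fingerprint <- function(flat, n_bits = 512L) {
  matrix(flat, ncol = n_bits, byrow = TRUE)
}

#' Vectorize a dataset of reactions as fingerprints
#'
#' Batch workhorse: computes the (optionally flattened) reaction
#' fingerprints for every instance of a dataset, caching per-molecule
#' fingerprints across reactions.
#'
#' @param dataset Dataset tibble (needs `reaction_smiles`).
#' @param n_bits,radius,products_only,n_products See
#'   [reaction_fingerprint()].
#' @param flatten Return an n x (8*n_bits) matrix instead of a list of
#'   8 x n_bits matrices.
#' @return Numeric matrix (if `flatten` or `products_only`) or a list of
#'   matrices.
#' @export
vectorize_fingerprints <- function(dataset, n_bits = 512L, radius = 2L,
                                   flatten = TRUE, products_only = FALSE,
                                   n_products = 1L) {
  # warm the per-molecule cache in one batch
  all_mols <- unique(unlist(purrr::map(dataset$reaction_smiles, split_reaction_smiles)))
  invisible(ecfp(all_mols, n_bits = n_bits, radius = radius))
  fps <- purrr::map(
    dataset$reaction_smiles, reaction_fingerprint,
    n_bits = n_bits, radius = radius,
    products_only = products_only, n_products = n_products
  )
  if (products_only) {
    return(do.call(rbind, fps))
  }
  if (flatten) {
    return(do.call(rbind, purrr::map(fps, flatten_fingerprint)))
  }
  fps
}
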