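# Independent brute-force oracles for the miner, plus small test utilities.
# These enumerate the full power set directly and never share code with the
# Apriori implementation they check.

ITEM_SEP <- "\x1f"

# every itemset of size <= max_len with support >= min_support, by
# exhaustive enumeration; returns named integer counts
brute_itemsets <- function(tx, min_support, max_len) {
  n <- length(tx)
  items <- sort(unique(unlist(tx)))
  out <- stats::setNames(integer(0), character(0))
  for (k in seq_len(min(max_len, length(items)))) {
    for (s in utils::combn(items, k, simplify = FALSE)) {
      ct <- sum(vapply(tx, function(t) all(s %in% t), logical(1)))
      if (ct / n >= min_support - 1e-12 && ct >= 1L) {
        out[[paste(s, collapse = ITEM_SEP)]] <- ct
      }
    }
  }
  out
}

# all single-category-consequent rules derivable from the brute itemsets
brute_rules <- function(tx, min_support, max_len, min_confidence,
                        category_items = c("CAT1", "CAT2", "CAT3", "CAT4")) {
  n <- length(tx)
  freq <- brute_itemsets(tx, min_support, max_len)
  keys <- strsplit(names(freq), ITEM_SEP, fixed = TRUE)
  rows <- list()
  for (i in seq_along(keys)) {
    s <- keys[[i]]
    in_cat <- s %in% category_items
    if (sum(in_cat) != 1L || length(s) < 2L) next
    lhs <- s[!in_cat]; rhs <- s[in_cat]
    lc <- freq[[paste(lhs, collapse = ITEM_SEP)]]
    if (is.null(lc)) next  # antecedent not frequent -> not emitted
    conf <- freq[[i]] / lc
    if (conf < min_confidence - 1e-12) next
    rc <- freq[[rhs]]
    rows[[length(rows) + 1L]] <- data.frame(
      lhs_key = paste(lhs, collapse = ITEM_SEP), rhs = rhs,
      support = freq[[i]] / n, confidence = conf,
      lift = conf * n / rc, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(lhs_key = character(0), rhs = character(0),
                      support = numeric(0), confidence = numeric(0),
                      lift = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$rhs, out$lhs_key), , drop = FALSE]
}

# abstract transactions with one planted category label each
make_labeled_txns <- function(n_txns, n_items, density, seed,
                              categories = c("CAT2", "CAT3")) {
  tx <- generate_transactions(n_txns, n_items, density, seed)
  set.seed(seed + 10000L)
  labels <- sample(categories, n_txns, replace = TRUE)
  Map(function(t, l) c(t, l), tx, labels)
}

# bare fingerprint constructor for classifier tests
new_fp <- function(id, feats) {
  structure(list(id = id, features = sort(unique(as.character(feats)))),
            class = "atompair_fp")
}

# permute the atom order of a molgraph (for invariance tests)
permute_molgraph <- function(g, perm) {
  inv <- order(perm)  # new index of old atom i is inv[i]
  bonds <- g$bonds
  bonds$a <- inv[bonds$a]; bonds$b <- inv[bonds$b]
  structure(list(id = g$id,
                 elements = g$elements[perm],
                 aromatic = g$aromatic[perm],
                 heavy_neighbors = g$heavy_neighbors[perm],
                 pi_electrons = g$pi_electrons[perm],
                 bonds = bonds), class = "molgraph")
}

# a small pool of parseable structures exercising rings, branches,
# heteroatoms, salts and both nitro spellings
TEST_SMILES <- c(
  benzene = "c1ccccc1",
  toluene = "Cc1ccccc1",
  nitrobenzene = "O=[N+]([O-])c1ccccc1",
  nitrobenzene2 = "O=N(=O)c1ccccc1",
  tnt_like = "Cc1c(cc(cc1[N+](=O)[O-])[N+](=O)[O-])[N+](=O)[O-]",
  aniline = "Nc1ccccc1",
  phenol = "Oc1ccccc1",
  acetic = "CC(=O)O",
  acetate_salt = "CC(=O)[O-].[Na+]",
  hexane = "CCCCCC",
  cyclohexane = "C1CCCCC1",
  acetonitrile = "CC#N",
  naphthalene = "c1ccc2ccccc2c1",
  pyridine = "c1ccncc1",
  furan_kek = "C1=CC=CO1",
  styrene = "C=Cc1ccccc1"
)
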