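# Synthetic hazard datasets with planted, category-associated motifs.
#
# Each chemical is a hydrocarbon scaffold decorated with a substituent
# written as a SMILES prefix.  With probability `fidelity` the substituent
# is the motif planted for the chemical's category, otherwise a plain alkyl
# decoy; motifs use elements absent from every scaffold and decoy (Cl, N/O,
# S, ether O), so at fidelity 1.0 each motif's atom pairs are perfectly
# associated with its category.  LC50 values are drawn log-uniformly inside
# the assigned category's GHS band, so they re-discretise exactly.

SYNTH_SCAFFOLDS <- c(
  benzene = "c1ccccc1",
  toluene = "Cc1ccccc1",
  xylene = "Cc1ccccc1C",
  ethylbenzene = "CCc1ccccc1",
  styrene = "C=Cc1ccccc1",
  naphthalene = "c1ccc2ccccc2c1",
  biphenyl = "c1ccc(cc1)-c1ccccc1",
  hexane = "CCCCCC",
  cyclohexane = "C1CCCCC1",
  methylcyclohexane = "CC1CCCCC1"
)

SYNTH_MOTIFS <- c(
  CAT1 = "ClC(Cl)(Cl)",   # trichloromethyl
  CAT2 = "[O-][N+](=O)",  # nitro (charge-separated)
  CAT3 = "CS",            # methylthio
  CAT4 = "CCO"            # ethoxy
)

SYNTH_DECOYS <- c("C", "CC", "CCC")

# GHS band bounds (mg/L); sampling stays strictly inside (lo, hi]
GHS_BOUNDS <- list(CAT1 = c(0.01, 1), CAT2 = c(1, 10),
                   CAT3 = c(10, 100), CAT4 = c(100, 10000))

#' Configuration for the synthetic hazard dataset generator
#'
#' @param n_chemicals number of chemicals (default 60).
#' @param mix proportions over CAT1..CAT4, summing to 1; the default
#'   `(0.10, 0.30, 0.40, 0.20)` mirrors the skew of real acute fish LC50
#'   collections, where CAT3 dominates, CAT2 follows, and CAT1/CAT4 are
#'   sparse.
#' @param fidelity probability in `(0.5, 1]` that a chemical carries its
#'   category's planted motif rather than an alkyl decoy (default 0.9).
#' @param motifs named character: SMILES prefix fragment per category.
#' @param scaffolds named character vector of scaffold SMILES.
#' @param seed integer seed; generation is fully deterministic given the
#'   config.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_chemicals = 60L, mix = c(0.10, 0.30, 0.40, 0.20),
                         fidelity = 0.9, motifs = SYNTH_MOTIFS,
                         scaffolds = SYNTH_SCAFFOLDS, seed = 1L) {
  stopifnot(n_chemicals >= 4L, length(mix) == 4L, all(mix >= 0),
            abs(sum(mix) - 1) < 1e-9, fidelity > 0.5, fidelity <= 1)
  names(mix) <- GHS_CATEGORIES
  planted <- GHS_CATEGORIES[GHS_CATEGORIES %in% names(motifs)]
  if (any(mix[planted] <= 0)) {
    stop("zero proportion for a category with a planted motif", call. = FALSE)
  }
  structure(list(n_chemicals = as.integer(n_chemicals), mix = mix,
                 fidelity = fidelity, motifs = motifs, scaffolds = scaffolds,
                 seed = as.integer(seed)), class = "synth_config")
}

# largest-remainder allocation of n into proportions p (exact, deterministic)
largest_remainder <- function(n, p) {
  raw <- n * p
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- raw - counts
    extra <- order(-frac, seq_along(p))[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  as.integer(counts)
}

# Deterministic scaffold assignment in congeneric blocks.  Real acute-fish
# hazard collections (munitions series especially) are families of close
# analogues, so each (category, scaffold) cell gets a block of replicate
# structures.  Blocks are sized above the per-category share of a stratified
# 5-fold split, and consecutive cells cycle through a scaffold subset large
# enough that no scaffold sits in a single category.  Two consequences, by
# construction at fidelity 1: every held-out chemical keeps an identical
# analogue in training, and no scaffold-only feature can be perfectly
# associated with a category — so every confidence-1 rule is category-
# faithful and cross-validation recovers the planted signal exactly.
assign_scaffolds <- function(counts, scaffold_names) {
  cells_per_cat <- ifelse(counts == 0L, 0L,
                          pmax(1L, counts %/% pmax(8L, ceiling(counts / 4))))
  total_cells <- sum(cells_per_cat)
  m <- min(length(scaffold_names), max(2L, total_cells %/% 2L))
  use <- scaffold_names[floor(seq(1, length(scaffold_names),
                                  length.out = m))]
  out <- character(0)
  cell <- 0L
  for (c in seq_along(counts)) {
    if (counts[[c]] == 0L) next
    # spread the category's chemicals over its cells as evenly as possible
    cell_of_chem <- (seq_len(counts[[c]]) - 1L) %% cells_per_cat[[c]] + 1L
    out <- c(out, use[(cell + cell_of_chem - 1L) %% m + 1L])
    cell <- cell + cells_per_cat[[c]]
  }
  out
}

#' Generate a synthetic hazard dataset with planted toxicophores
#'
#' Produces `n_chemicals` records.  Category sizes follow the configured mix
#' under largest-remainder rounding (exact to ±1).  Scaffolds are assigned
#' in congeneric blocks — several analogues of the same scaffold per
#' (category, scaffold) cell, with every scaffold spanning at least two
#' categories — mirroring the analogue-series structure of real hazard
#' collections and guaranteeing that scaffold identity alone never predicts
#' the category, even within a cross-validation training fold.  Alongside
#' the records the generator reports, per category, the set of atom-pair
#' features that involve at least one motif atom in a motif-bearing molecule
#' — the ground truth a miner is expected to recover.
#'
#' @param cfg a [synth_config()].
#' @return list with `records` (hazard table: `id`, `smiles`, `lc50`,
#'   `category`), `motif_features` (named list: category -> character vector
#'   of feature keys), and `assignments` (per chemical: scaffold, motif
#'   carried, whether it is the planted one).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- cfg$n_chemicals
  counts <- largest_remainder(n, cfg$mix)
  category <- rep(GHS_CATEGORIES, counts)
  scaffold <- assign_scaffolds(counts, names(cfg$scaffolds))

  with_seed(cfg$seed, {
    planted <- stats::runif(n) <= cfg$fidelity
    decoy <- sample(SYNTH_DECOYS, n, replace = TRUE)
    motif <- ifelse(planted, unname(cfg$motifs[category]), decoy)
    lc50 <- vapply(category, function(cc) {
      b <- GHS_BOUNDS[[cc]]
      exp(stats::runif(1, log(b[[1]] * 1.02), log(b[[2]] * 0.98)))
    }, numeric(1))
  })

  smiles <- paste0(motif, unname(cfg$scaffolds[scaffold]))
  id <- sprintf("syn%03d", seq_len(n))
  records <- data.frame(id = id, smiles = smiles, lc50 = unname(lc50),
                        category = category, stringsAsFactors = FALSE)

  motif_sizes <- vapply(cfg$motifs, function(m) n_atoms(parse_smiles(m)),
                        integer(1))
  motif_features <- stats::setNames(
    vector("list", length(cfg$motifs)), names(cfg$motifs))
  for (i in seq_len(n)) {
    if (!planted[[i]]) next
    cc <- category[[i]]
    g <- parse_smiles(smiles[[i]], id[[i]])
    tab <- atom_pair_table(g)
    m <- motif_sizes[[cc]]
    touch <- tab$key[tab$i <= m | tab$j <= m]
    motif_features[[cc]] <- union(motif_features[[cc]], touch)
  }
  motif_features <- lapply(motif_features, function(x) sort(unique(x)))

  list(records = records,
       motif_features = motif_features,
       assignments = data.frame(id = id, category = category,
                                scaffold = scaffold, motif = motif,
                                planted = planted, stringsAsFactors = FALSE))
}

#' Write a synthetic dataset to disk
#'
#' Emits the hazard CSV in the [read_hazard_csv()] dialect plus a JSON
#' sidecar with the planted ground truth (motif features per category and
#' per-chemical assignments).
#'
#' @param ds result of [generate_dataset()].
#' @param csv_path output CSV path.
#' @param json_path output JSON sidecar path (default: csv path with a
#'   `.truth.json` suffix).
#' @export
write_synth_dataset <- function(ds, csv_path,
                                json_path = sub("\\.csv$", ".truth.json",
                                                csv_path)) {
  df <- data.frame(id = ds$records$id, smiles = ds$records$smiles,
                   lc50_mg_per_L = format(ds$records$lc50, digits = 15),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(motif_features = ds$motif_features,
                            assignments = ds$assignments),
                       json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(csv_path)
}

#' Generate abstract random transactions
#'
#' Presence/absence baskets over `n_items` abstract items, each present in
#' each transaction independently with probability `density`.  Used to
#' exercise the miner against the brute-force oracle without any chemistry.
#'
#' @param n_txns number of transactions.
#' @param n_items number of distinct items.
#' @param density inclusion probability in `(0, 1]` (1 puts every item in
#'   every transaction).
#' @param seed integer seed.
#' @return list of character vectors (possibly empty).
#' @export
generate_transactions <- function(n_txns, n_items, density, seed = 1L) {
  stopifnot(n_txns >= 1L, n_items >= 1L, density > 0, density <= 1)
  items <- sprintf("i%02d", seq_len(n_items))
  with_seed(seed, {
    lapply(seq_len(n_txns), function(.)
      items[stats::runif(n_items) < density])
  })
}
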