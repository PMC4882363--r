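# From-scratch Apriori frequent-itemset mining and category-consequent rule
# generation.  Items are opaque strings: rendered atom-pair features plus one
# GHS category label per transaction.  All supports are kept as exact integer
# counts over the transaction total, so confidence/lift identities hold to
# machine precision and brute-force oracle comparisons are exact.

ITEM_SEP <- "\x1f"

#' Build market-basket transactions from hazard records and fingerprints
#'
#' One transaction per chemical: its atom-pair features plus exactly one
#' category item (`"CAT1"`..`"CAT4"`).  The item universe is the set of
#' features observed in the dataset; an optional minimum-count filter drops
#' features present in fewer than `min_count` chemicals.
#'
#' @param records hazard table as returned by [read_hazard_csv()] /
#'   [hazard_records()].
#' @param fps named list of `atompair_fp`, covering every record id.
#' @param min_count drop features occurring in fewer than this many
#'   chemicals (default 1, i.e. keep all observed features).
#' @return an object of class `tox_transactions`: list with `id`,
#'   `items` (list of character vectors, category item included) and
#'   `category` (named character).
#' @export
build_transactions <- function(records, fps, min_count = 1L) {
  missing <- setdiff(records$id, names(fps))
  if (length(missing) > 0L) {
    stop(sprintf("missing fingerprint(s) for: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  feats <- lapply(records$id, function(i) fps[[i]]$features)
  if (min_count > 1L) {
    tab <- table(unlist(lapply(feats, unique)))
    keep <- names(tab)[tab >= min_count]
    feats <- lapply(feats, function(f) f[f %in% keep])
  }
  items <- Map(function(f, cat) c(f, cat), feats, records$category)
  structure(list(id = records$id,
                 items = unname(items),
                 category = stats::setNames(records$category, records$id)),
            class = "tox_transactions")
}

#' @export
print.tox_transactions <- function(x, ...) {
  cat(sprintf("<tox_transactions: %d chemicals, %d distinct items>\n",
              length(x$id), length(unique(unlist(x$items)))))
  invisible(x)
}

#' Export transactions as a basket CSV
#'
#' One row per chemical: id and the semicolon-joined item strings.  Useful
#' for cross-checking the miner against independent implementations.
#'
#' @param txns a `tox_transactions`.
#' @param path output CSV path.
#' @export
write_basket_csv <- function(txns, path) {
  stopifnot(inherits(txns, "tox_transactions"))
  df <- data.frame(id = txns$id,
                   items = vapply(txns$items, paste, character(1),
                                  collapse = ";"),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

item_lists_of <- function(txns) {
  if (inherits(txns, "tox_transactions")) txns$items
  else if (is.list(txns)) lapply(txns, as.character)
  else stop("transactions must be a tox_transactions or a list of character vectors",
            call. = FALSE)
}

# smallest integer count c such that c / n >= min_support
min_count_for <- function(min_support, n) {
  max(1L, as.integer(ceiling(min_support * n - 1e-9)))
}

#' Mine frequent itemsets with Apriori
#'
#' Level-wise candidate generation with downward-closure pruning (every
#' (k-1)-subset of a candidate must itself be frequent).  Supports are exact:
#' the result carries integer occurrence counts over the transaction total.
#'
#' @param txns a `tox_transactions` or a plain list of character vectors.
#' @param min_support minimum support in `(0, 1]`.
#' @param max_len maximum itemset size (>= 1).
#' @return an object of class `frequent_itemsets`: data frame with columns
#'   `items` (list of sorted character vectors), `size`, `count`, `support`;
#'   attributes `n_transactions` and a `lookup` environment mapping itemset
#'   keys to row numbers.
#' @export
frequent_itemsets <- function(txns, min_support, max_len = 5L) {
  item_lists <- item_lists_of(txns)
  n <- length(item_lists)
  if (n == 0L) stop("no transactions", call. = FALSE)
  stopifnot(min_support > 0, min_support <= 1, max_len >= 1L)
  min_count <- min_count_for(min_support, n)

  universe <- sort(unique(unlist(item_lists)))
  M <- matrix(FALSE, nrow = n, ncol = length(universe))
  for (t in seq_len(n)) {
    M[t, match(unique(item_lists[[t]]), universe)] <- TRUE
  }
  counts1 <- as.integer(colSums(M))
  keep <- counts1 >= min_count

  out_items <- list(); out_count <- integer(0)

  # level 1
  lvl_items <- matrix(which(keep), nrow = 1L)   # item indices, cols sorted
  lvl_cov <- M[, keep, drop = FALSE]
  lvl_counts <- counts1[keep]
  freq_keys <- new.env(parent = emptyenv())

  k <- 1L
  while (ncol(lvl_items) > 0L) {
    keys <- apply(lvl_items, 2L, paste, collapse = ITEM_SEP)
    for (ii in seq_along(keys)) assign(keys[[ii]], TRUE, envir = freq_keys)
    out_items <- c(out_items,
                   lapply(seq_len(ncol(lvl_items)),
                          function(ci) universe[lvl_items[, ci]]))
    out_count <- c(out_count, lvl_counts)
    if (k >= max_len) break

    # candidate generation: join columns sharing the first k-1 items... the
    # classic join shares the first k-1 of k items; here levels hold k items
    prefix <- if (k == 1L) rep("", ncol(lvl_items))
              else apply(lvl_items[seq_len(k - 1L), , drop = FALSE], 2L,
                         paste, collapse = ITEM_SEP)
    groups <- split(seq_len(ncol(lvl_items)), prefix)
    cand_items <- list(); cand_cov <- list(); cand_counts <- integer(0)
    for (grp in groups) {
      if (length(grp) < 2L) next
      last <- lvl_items[k, grp]
      o <- order(last)
      grp <- grp[o]; last <- last[o]
      pr <- utils::combn(seq_along(grp), 2L)
      for (p in seq_len(ncol(pr))) {
        i <- grp[pr[1L, p]]; j <- grp[pr[2L, p]]
        cand <- c(lvl_items[, i], lvl_items[k, j])
        # downward closure: check the k-1 subsets that drop a shared item
        ok <- TRUE
        if (k >= 2L) {
          for (drop_pos in seq_len(k - 1L)) {
            sk <- paste(cand[-drop_pos], collapse = ITEM_SEP)
            if (!exists(sk, envir = freq_keys, inherits = FALSE)) {
              ok <- FALSE; break
            }
          }
        }
        if (!ok) next
        cv <- lvl_cov[, i] & lvl_cov[, j]
        ct <- as.integer(sum(cv))
        if (ct >= min_count) {
          cand_items[[length(cand_items) + 1L]] <- cand
          cand_cov[[length(cand_cov) + 1L]] <- cv
          cand_counts[[length(cand_counts) + 1L]] <- ct
        }
      }
    }
    if (length(cand_items) == 0L) break
    lvl_items <- matrix(unlist(cand_items), nrow = k + 1L)
    lvl_cov <- matrix(unlist(cand_cov), nrow = n)
    lvl_counts <- cand_counts
    k <- k + 1L
  }

  df <- data.frame(size = lengths(out_items), count = out_count,
                   support = out_count / n)
  df$items <- out_items
  key <- vapply(out_items, paste, character(1), collapse = ITEM_SEP)
  ord <- order(df$size, key)
  df <- df[ord, c("items", "size", "count", "support")]
  rownames(df) <- NULL
  lookup <- new.env(parent = emptyenv())
  sorted_keys <- key[ord]
  for (ii in seq_along(sorted_keys)) assign(sorted_keys[[ii]], ii, envir = lookup)
  structure(df, n_transactions = n, lookup = lookup, min_support = min_support,
            max_len = max_len, class = c("frequent_itemsets", "data.frame"))
}

itemset_count <- function(itemsets, items) {
  key <- paste(sort(items), collapse = ITEM_SEP)
  row <- get0(key, envir = attr(itemsets, "lookup"), inherits = FALSE)
  if (is.null(row)) NA_integer_ else itemsets$count[[row]]
}

#' Generate category-consequent association rules from frequent itemsets
#'
#' Rules have a non-empty antecedent of atom-pair features and a single GHS
#' category consequent.  Confidence is the exact conditional probability
#' `support(lhs ∪ {rhs}) / support(lhs)`; lift is
#' `confidence / support(rhs)`.  Rules below `min_confidence` are dropped.
#' A category whose label never reaches the support threshold simply yields
#' no rules.
#'
#' @param itemsets a `frequent_itemsets` object.
#' @param category_items character vector of consequent labels (default the
#'   four GHS categories).
#' @param min_confidence minimum confidence in `(0, 1]` (default 0.75).
#' @return an object of class `tox_ruleset`; see [ruleset_rules()].
#' @export
generate_rules <- function(itemsets, category_items = GHS_CATEGORIES,
                           min_confidence = 0.75) {
  stopifnot(inherits(itemsets, "frequent_itemsets"),
            min_confidence > 0, min_confidence <= 1)
  n <- attr(itemsets, "n_transactions")

  cat_counts <- vapply(category_items, function(ci) {
    ct <- itemset_count(itemsets, ci)
    if (is.na(ct)) 0L else ct
  }, integer(1))

  lhs <- list(); rhs <- character(0)
  rule_count <- integer(0); lhs_count <- integer(0); rhs_count <- integer(0)
  for (r in seq_len(nrow(itemsets))) {
    its <- itemsets$items[[r]]
    in_cat <- its %in% category_items
    if (sum(in_cat) != 1L || length(its) < 2L) next
    cat_item <- its[in_cat]
    ante <- its[!in_cat]
    lc <- itemset_count(itemsets, ante)
    # antecedent is frequent by downward closure; guard anyway
    if (is.na(lc)) next
    ct <- itemsets$count[[r]]
    # exact threshold test: ct / lc >= min_confidence
    if (ct < min_confidence * lc - 1e-9) next
    lhs[[length(lhs) + 1L]] <- ante
    rhs[[length(rhs) + 1L]] <- cat_item
    rule_count[[length(rule_count) + 1L]] <- ct
    lhs_count[[length(lhs_count) + 1L]] <- lc
    rhs_count[[length(rhs_count) + 1L]] <- cat_counts[[cat_item]]
  }

  rules <- data.frame(
    rhs = rhs,
    size = lengths(lhs),
    rule_count = rule_count, lhs_count = lhs_count, rhs_count = rhs_count,
    stringsAsFactors = FALSE
  )
  rules$lhs <- lhs
  rules$lhs_key <- vapply(lhs, paste, character(1), collapse = ITEM_SEP)
  rules$support <- rules$rule_count / n
  rules$confidence <- rules$rule_count / rules$lhs_count
  rules$lift <- rules$confidence * n / rules$rhs_count
  ord <- order(rules$rhs, rules$size, rules$lhs_key)
  rules <- rules[ord, c("lhs", "rhs", "size", "rule_count", "lhs_count",
                        "rhs_count", "support", "confidence", "lift",
                        "lhs_key")]
  rownames(rules) <- NULL

  structure(list(
    rules = rules,
    n_transactions = n,
    category_counts = cat_counts,
    params = list(min_support = attr(itemsets, "min_support"),
                  min_confidence = min_confidence,
                  max_len = attr(itemsets, "max_len"))
  ), class = "tox_ruleset")
}

#' Rules table of a rule set
#'
#' @param ruleset a `tox_ruleset`.
#' @return the rules data frame: `lhs` (list of feature strings), `rhs`,
#'   `size`, exact counts, `support`, `confidence`, `lift`.
#' @export
ruleset_rules <- function(ruleset) {
  stopifnot(inherits(ruleset, "tox_ruleset"))
  ruleset$rules
}

#' @export
print.tox_ruleset <- function(x, ...) {
  tab <- table(factor(x$rules$rhs, levels = GHS_CATEGORIES))
  cat(sprintf("<tox_ruleset: %d rules over %d transactions (min_support=%g, min_confidence=%g)>\n",
              nrow(x$rules), x$n_transactions,
              x$params$min_support, x$params$min_confidence))
  cat("  rules per category:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Top rules for a category, ordered by lift
#'
#' Rules with the given consequent sorted by lift (descending), ties broken
#' by confidence (descending), then smaller antecedent, then lexicographic
#' antecedent rendering — a total order, so the result is reproducible.
#'
#' @param ruleset a `tox_ruleset`.
#' @param category a category label, e.g. `"CAT2"`.
#' @param by ordering statistic; only `"lift"` is supported.
#' @return the ordered subset of the rules table (possibly empty).
#' @export
top_rules <- function(ruleset, category, by = "lift") {
  stopifnot(inherits(ruleset, "tox_ruleset"), by == "lift")
  r <- ruleset$rules[ruleset$rules$rhs == category, , drop = FALSE]
  if (nrow(r) == 0L) return(r)
  r <- r[order(-r$lift, -r$confidence, r$size, r$lhs_key), , drop = FALSE]
  rownames(r) <- NULL
  r
}

#' Minimal equivalent rule (toxicophore reduction)
#'
#' A longer rule adds no information over a shorter one when both have the
#' same consequent, identical support, confidence and lift, and the shorter
#' antecedent is a subset of the longer.  `minimize_rule` returns the rule
#' with the smallest antecedent among all such sub-rules in the rule set
#' (applied transitively); a rule with no equal-statistics sub-rule is its
#' own minimizer, so the operation is idempotent.
#'
#' @param rule a single row of the rules table (data frame with one row), or
#'   an integer row index into `ruleset_rules(ruleset)`.
#' @param ruleset the `tox_ruleset` containing the rule.
#' @return the minimizing rule as a one-row data frame.
#' @export
minimize_rule <- function(rule, ruleset) {
  stopifnot(inherits(ruleset, "tox_ruleset"))
  rules <- ruleset$rules
  if (is.numeric(rule)) rule <- rules[rule, , drop = FALSE]
  stopifnot(is.data.frame(rule), nrow(rule) == 1L)
  lhs <- rule$lhs[[1]]
  # equal statistics exactly: same joint count and same antecedent count
  # (equal support => equal rule_count; equal confidence then forces equal
  # lhs_count; lift equality follows from the shared consequent)
  cand <- which(rules$rhs == rule$rhs &
                  rules$rule_count == rule$rule_count &
                  rules$lhs_count == rule$lhs_count &
                  rules$size <= length(lhs))
  ok <- cand[vapply(cand, function(i) all(rules$lhs[[i]] %in% lhs), logical(1))]
  if (length(ok) == 0L) return(rule)
  best <- ok[order(rules$size[ok], rules$lhs_key[ok])][1L]
  out <- rules[best, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Minimise every rule in a rule set
#'
#' @param ruleset a `tox_ruleset`.
#' @return integer vector: for each rule, the row index of its minimizer.
#' @export
minimize_rules <- function(ruleset) {
  rules <- ruleset$rules
  vapply(seq_len(nrow(rules)), function(i) {
    m <- minimize_rule(rules[i, , drop = FALSE], ruleset)
    which(rules$lhs_key == m$lhs_key & rules$rhs == m$rhs)[1L]
  }, integer(1))
}

#' Serialise a rule set to JSON
#'
#' Writes every rule (antecedent feature strings, consequent, exact counts
#' and derived statistics) plus the mining parameters; the counts make the
#' round trip through [read_ruleset_json()] lossless.
#'
#' @param ruleset a `tox_ruleset`.
#' @param path output file.
#' @export
write_ruleset_json <- function(ruleset, path) {
  stopifnot(inherits(ruleset, "tox_ruleset"))
  r <- ruleset$rules
  obj <- list(
    n_transactions = ruleset$n_transactions,
    category_counts = as.list(ruleset$category_counts),
    params = ruleset$params,
    rules = lapply(seq_len(nrow(r)), function(i) list(
      lhs = r$lhs[[i]], rhs = r$rhs[[i]],
      rule_count = r$rule_count[[i]], lhs_count = r$lhs_count[[i]],
      rhs_count = r$rhs_count[[i]],
      support = r$support[[i]], confidence = r$confidence[[i]],
      lift = r$lift[[i]]
    ))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ruleset_json
#' @export
read_ruleset_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  n <- obj$n_transactions
  rl <- obj$rules
  lhs <- lapply(rl, function(x) sort(unlist(x$lhs)))
  rules <- data.frame(
    rhs = vapply(rl, `[[`, character(1), "rhs"),
    size = lengths(lhs),
    rule_count = vapply(rl, function(x) as.integer(x$rule_count), integer(1)),
    lhs_count = vapply(rl, function(x) as.integer(x$lhs_count), integer(1)),
    rhs_count = vapply(rl, function(x) as.integer(x$rhs_count), integer(1)),
    stringsAsFactors = FALSE
  )
  rules$lhs <- lhs
  rules$lhs_key <- vapply(lhs, paste, character(1), collapse = ITEM_SEP)
  rules$support <- rules$rule_count / n
  rules$confidence <- rules$rule_count / rules$lhs_count
  rules$lift <- rules$confidence * n / rules$rhs_count
  ord <- order(rules$rhs, rules$size, rules$lhs_key)
  rules <- rules[ord, c("lhs", "rhs", "size", "rule_count", "lhs_count",
                        "rhs_count", "support", "confidence", "lift",
                        "lhs_key")]
  rownames(rules) <- NULL
  cc <- vapply(obj$category_counts, function(x) as.integer(x), integer(1))
  structure(list(rules = rules, n_transactions = as.integer(n),
                 category_counts = cc,
                 params = lapply(obj$params, function(x) x)),
            class = "tox_ruleset")
}
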