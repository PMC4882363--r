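# The fitted-model surface: tox_apriori() ties parsing, fingerprinting,
# transaction building, mining and prediction together in one classed object.

#' Fit an atom-pair association-rule model of GHS acute aquatic toxicity
#'
#' Parses every structure, computes presence/absence atom-pair fingerprints,
#' builds one market-basket transaction per chemical (features plus its GHS
#' category), mines frequent itemsets with Apriori and keeps the
#' single-category-consequent rules at the confidence threshold.  Each
#' training chemical is then classified by its best matching rule; chemicals
#' matched by no rule are the ones the Tanimoto surrogate handles at
#' prediction time.
#'
#' @param data a hazard table (data frame with columns `id`, `smiles`,
#'   `lc50`; `category` is derived) or a path to a CSV in the
#'   [read_hazard_csv()] dialect.
#' @param min_support minimum itemset support (default 0.05, i.e. roughly
#'   "at least 3 chemicals" at the scale of a ~57-compound dataset).
#' @param min_confidence minimum rule confidence (default 0.75).
#' @param max_len maximum antecedent size in items (default 5; itemsets up
#'   to `max_len + 1` including the category item are mined).
#' @param max_distance maximum topological distance for atom pairs
#'   (default 15 bonds).
#' @param min_feature_count drop features seen in fewer than this many
#'   chemicals before mining (default 1 = keep all observed).
#' @return an object of class `tox_apriori` with components `records`,
#'   `fingerprints`, `transactions`, `ruleset`, `train_pred` (named
#'   character, `NA` for rule-uncovered chemicals) and `params`.
#' @examples
#' set.seed(1)
#' ds <- generate_dataset(synth_config(n_chemicals = 24, seed = 7))
#' fit <- tox_apriori(ds$records, max_len = 2)
#' fit
#' @export
tox_apriori <- function(data, min_support = 0.05, min_confidence = 0.75,
                        max_len = 5L, max_distance = 15L,
                        min_feature_count = 1L) {
  if (is.character(data) && length(data) == 1L) data <- read_hazard_csv(data)
  stopifnot(is.data.frame(data), all(c("id", "smiles", "lc50") %in% names(data)))
  if (!"category" %in% names(data)) data$category <- ghs_category(data$lc50)
  stopifnot(min_support > 0, min_support <= 1,
            min_confidence > 0, min_confidence <= 1,
            max_len >= 1L, max_distance >= 1L)

  graphs <- Map(parse_smiles, data$smiles, data$id)
  fps <- fingerprint_all(graphs, max_distance = max_distance)
  txns <- build_transactions(data, fps, min_count = min_feature_count)
  itemsets <- frequent_itemsets(txns, min_support = min_support,
                                max_len = max_len + 1L)
  ruleset <- generate_rules(itemsets, min_confidence = min_confidence)

  train_pred <- stats::setNames(rep(NA_character_, nrow(data)), data$id)
  for (i in seq_len(nrow(data))) {
    hit <- predict_by_rules(fps[[data$id[[i]]]], ruleset)
    if (!is.null(hit)) train_pred[[data$id[[i]]]] <- hit$category
  }

  structure(list(
    records = data,
    fingerprints = fps,
    transactions = txns,
    ruleset = ruleset,
    train_pred = train_pred,
    params = list(min_support = min_support, min_confidence = min_confidence,
                  max_len = max_len, max_distance = max_distance,
                  min_feature_count = min_feature_count),
    call = match.call()
  ), class = "tox_apriori")
}

#' @export
print.tox_apriori <- function(x, ...) {
  cat("Atom-pair association-rule model of GHS acute aquatic toxicity\n")
  cat(sprintf("  chemicals: %d   rules: %d   rule-covered: %d/%d\n",
              nrow(x$records), nrow(x$ruleset$rules),
              sum(!is.na(x$train_pred)), nrow(x$records)))
  cat(sprintf("  params: min_support=%g, min_confidence=%g, max_len=%d, max_distance=%d\n",
              x$params$min_support, x$params$min_confidence,
              x$params$max_len, x$params$max_distance))
  invisible(x)
}

#' @export
summary.tox_apriori <- function(object, top_n = 3L, ...) {
  rules <- object$ruleset$rules
  per_cat <- lapply(GHS_CATEGORIES, function(cc) top_rules(object$ruleset, cc))
  names(per_cat) <- GHS_CATEGORIES
  structure(list(
    n_chemicals = nrow(object$records),
    category_counts = table(factor(object$records$category,
                                   levels = GHS_CATEGORIES)),
    n_rules = nrow(rules),
    rules_per_category = table(factor(rules$rhs, levels = GHS_CATEGORIES)),
    covered = sum(!is.na(object$train_pred)),
    top_rules = lapply(per_cat, utils::head, n = top_n),
    params = object$params
  ), class = "summary.tox_apriori")
}

#' @export
print.summary.tox_apriori <- function(x, ...) {
  cat("Atom-pair association-rule model of GHS acute aquatic toxicity\n\n")
  cat(sprintf("Chemicals: %d\n", x$n_chemicals))
  print(x$category_counts)
  cat(sprintf("\nRules (confidence >= %g): %d\n", x$params$min_confidence,
              x$n_rules))
  print(x$rules_per_category)
  cat(sprintf("\nRule-covered chemicals: %d/%d (%.0f%%)\n", x$covered,
              x$n_chemicals, 100 * x$covered / x$n_chemicals))
  for (cc in GHS_CATEGORIES) {
    tr <- x$top_rules[[cc]]
    cat(sprintf("\nTop rules for %s by lift:\n", cc))
    if (nrow(tr) == 0L) {
      cat("  (no rules at this confidence)\n")
    } else {
      for (i in seq_len(nrow(tr))) {
        cat(sprintf("  {%s} => %s  supp=%.3f conf=%.3f lift=%.2f\n",
                    paste(tr$lhs[[i]], collapse = ", "), tr$rhs[[i]],
                    tr$support[[i]], tr$confidence[[i]], tr$lift[[i]]))
      }
    }
  }
  invisible(x)
}

#' Rule statistics of a fitted model
#'
#' `coef()` returns the mined rules with their support, confidence and lift
#' — the fitted "coefficients" of the model.
#'
#' @param object a `tox_apriori` fit.
#' @param ... unused.
#' @return data frame with one row per rule: `antecedent` (feature strings
#'   joined by `" & "`), `consequent`, `size`, `support`, `confidence`,
#'   `lift`.
#' @export
coef.tox_apriori <- function(object, ...) {
  r <- object$ruleset$rules
  data.frame(
    antecedent = vapply(r$lhs, paste, character(1), collapse = " & "),
    consequent = r$rhs, size = r$size, support = r$support,
    confidence = r$confidence, lift = r$lift, stringsAsFactors = FALSE
  )
}

#' Predict GHS categories for new structures
#'
#' @param object a `tox_apriori` fit.
#' @param newdata a data frame with `id` and `smiles` columns, a (optionally
#'   named) character vector of SMILES, or a named list of `atompair_fp`.
#'   Omitted: the training chemicals are predicted (each with itself
#'   excluded from the surrogate's training pool).
#' @param surrogate fall back to the Tanimoto nearest-neighbour surrogate
#'   for chemicals matching no rule (default `TRUE`).
#' @param ... unused.
#' @return data frame: `id`, `category` (or `"unclassifiable"`), `mode`
#'   (`rule`/`surrogate`/`none`), `confidence`, `lift`, `rule` (rendered
#'   antecedent or `NA`), `neighbor`, `distance`.
#' @export
predict.tox_apriori <- function(object, newdata = NULL, surrogate = TRUE,
                                ...) {
  loo <- is.null(newdata)
  fps <- if (loo) {
    object$fingerprints
  } else if (is.data.frame(newdata)) {
    stopifnot(all(c("id", "smiles") %in% names(newdata)))
    fingerprint_all(stats::setNames(newdata$smiles, newdata$id),
                    max_distance = object$params$max_distance)
  } else if (is.character(newdata)) {
    ids <- names(newdata)
    if (is.null(ids)) ids <- sprintf("query%d", seq_along(newdata))
    fingerprint_all(stats::setNames(newdata, ids),
                    max_distance = object$params$max_distance)
  } else if (is.list(newdata)) {
    newdata
  } else stop("unsupported newdata type", call. = FALSE)

  rows <- lapply(names(fps), function(id) {
    training <- object$fingerprints
    if (loo) training <- training[setdiff(names(training), id)]
    p <- predict_chemical(fps[[id]], object$ruleset, training,
                          object$train_pred, surrogate = surrogate)
    data.frame(id = id, category = p$category, mode = p$mode,
               confidence = p$confidence, lift = p$lift,
               rule = if (is.null(p$rule)) NA_character_
                      else paste(p$rule$lhs[[1]], collapse = " & "),
               neighbor = p$neighbor, distance = p$distance,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scatterplot of rule statistics
#'
#' Support against confidence for every mined rule, point size scaled by
#' lift and colour by consequent category — the standard picture of a mined
#' rule population.
#'
#' @param x a `tox_apriori` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.tox_apriori <- function(x, ...) {
  r <- x$ruleset$rules
  if (nrow(r) == 0L) {
    stop("no rules to plot", call. = FALSE)
  }
  cols <- stats::setNames(c("#D55E00", "#E69F00", "#009E73", "#0072B2"),
                          GHS_CATEGORIES)
  graphics::plot(r$support, r$confidence,
                 cex = 0.5 + r$lift / max(r$lift),
                 col = cols[r$rhs], pch = 16,
                 xlab = "support", ylab = "confidence",
                 main = "Association rules: support vs confidence (size ~ lift)",
                 ylim = c(min(r$confidence) * 0.95, 1), ...)
  graphics::legend("bottomright", legend = names(cols), col = cols, pch = 16,
                   bty = "n")
  invisible(x)
}

#' Minimal-toxicophore table for a category
#'
#' Takes the top rules by lift for a category, replaces each by its minimal
#' equivalent rule (see [minimize_rule()]) and deduplicates — the table of
#' structural alerts the rule set supports.
#'
#' @param ruleset a `tox_ruleset` or `tox_apriori` fit.
#' @param category a GHS category label.
#' @param top_n how many top rules to minimise (default all).
#' @return data frame of unique minimal rules in top-lift order.
#' @export
toxicophore_table <- function(ruleset, category, top_n = Inf) {
  if (inherits(ruleset, "tox_apriori")) ruleset <- ruleset$ruleset
  tr <- top_rules(ruleset, category)
  if (nrow(tr) == 0L) return(tr)
  if (is.finite(top_n)) tr <- utils::head(tr, top_n)
  mins <- lapply(seq_len(nrow(tr)), function(i) {
    minimize_rule(tr[i, , drop = FALSE], ruleset)
  })
  out <- do.call(rbind, mins)
  out <- out[!duplicated(paste(out$lhs_key, out$rhs)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
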