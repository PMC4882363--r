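# Stratified k-fold cross-validation, confusion matrices and
# classification-rate reporting.

UNCLASSIFIED <- "unclassified"

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Stratified k-fold assignment
#'
#' Assigns each id to one of `k` folds, stratified by category where counts
#' permit: ids are shuffled within category (seeded) and dealt round-robin
#' into folds with a counter that carries across categories, so overall fold
#' sizes differ by at most one and every category is spread as evenly as its
#' count allows.
#'
#' @param ids character vector of unique ids.
#' @param categories category label per id.
#' @param k number of folds, `2 <= k <= length(ids)`.
#' @param seed integer seed; the assignment is a pure function of
#'   (ids, categories, k, seed).
#' @return named integer vector: fold (1..k) per id.
#' @export
kfold_split <- function(ids, categories, k, seed = 1L) {
  stopifnot(length(ids) == length(categories), !anyDuplicated(ids))
  n <- length(ids)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (k > n) stop(sprintf("k = %d exceeds the %d available chemicals", k, n),
                  call. = FALSE)
  fold <- stats::setNames(integer(n), ids)
  counter <- 0L
  with_seed(seed, {
    for (cat in sort(unique(categories))) {
      members <- ids[categories == cat]
      members <- sample(members, length(members))
      fold[members] <- (counter + seq_along(members) - 1L) %% k + 1L
      counter <- (counter + length(members)) %% k
    }
  })
  fold
}

#' Confusion matrix of GHS predictions
#'
#' Rows are ground-truth categories, columns the four predicted categories
#' plus an `unclassified` spill column for chemicals the model could not
#' place.
#'
#' @param truth ground-truth categories (`"CAT1"`..`"CAT4"`).
#' @param predicted predicted categories; anything outside the four labels
#'   (e.g. `"unclassifiable"`, `NA`) counts as unclassified.
#' @return a 4 x 5 integer matrix of class `tox_confusion`.
#' @export
confusion_matrix <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted),
            all(truth %in% GHS_CATEGORIES))
  predicted <- ifelse(predicted %in% GHS_CATEGORIES, predicted, UNCLASSIFIED)
  m <- table(factor(truth, levels = GHS_CATEGORIES),
             factor(predicted, levels = c(GHS_CATEGORIES, UNCLASSIFIED)))
  m <- unclass(m)
  storage.mode(m) <- "integer"
  structure(m, class = "tox_confusion")
}

#' @export
print.tox_confusion <- function(x, ...) {
  cat("Confusion matrix (rows: ground truth; columns: predicted)\n")
  print(unclass(x))
  cat(sprintf("classification rate: %.3f (%d/%d classified)\n",
              classification_rate(x), sum(diag(x[, GHS_CATEGORIES])),
              sum(x[, GHS_CATEGORIES])))
  invisible(x)
}

#' Classification rate of a confusion matrix
#'
#' Fraction of correctly classified chemicals among those the model
#' classified at all: the diagonal sum over the total of the 4 x 4 block,
#' excluding the `unclassified` spill column.
#'
#' @param cm a `tox_confusion` or a plain 4 x 4 (or 4 x 5) matrix with rows
#'   and columns ordered CAT1..CAT4.
#' @return rate in `[0, 1]`.
#' @export
classification_rate <- function(cm) {
  m <- unclass(cm)
  stopifnot(is.matrix(m), nrow(m) == 4L, ncol(m) >= 4L)
  block <- m[, seq_len(4L), drop = FALSE]
  total <- sum(block)
  if (total == 0L) stop("no classified chemicals in the confusion matrix",
                        call. = FALSE)
  sum(diag(block)) / total
}

#' Fivefold (k-fold) cross-validation of the rule model
#'
#' For each fold, rules are mined on the training chemicals only and the
#' held-out chemicals are predicted.  The fold's classification rate is, by
#' default, correct/total among the rule-classified test chemicals only —
#' the accounting that matches reporting a rate "for those chemicals the
#' model is capable of classifying"; `count_all = TRUE` switches the
#' denominator to every test chemical (surrogate and unclassifiable
#' included).  A fold whose training set yields no rules gets an `NA` rate,
#' is excluded from the mean, and triggers a warning.  The mean rate is the
#' unweighted mean over the defined fold rates.
#'
#' @param records hazard table (see [tox_apriori()]).
#' @param fingerprints optional pre-computed named list of `atompair_fp`
#'   (computed from `records$smiles` when omitted).
#' @param k number of folds (default 5).
#' @param seed fold-assignment seed (default 1).
#' @param min_support,min_confidence,max_len,max_distance mining parameters,
#'   as in [tox_apriori()].
#' @param surrogate also produce surrogate predictions for unmatched test
#'   chemicals (default `FALSE`; they enter the confusion matrices, and the
#'   rate only under `count_all`).
#' @param count_all use all test chemicals as the rate denominator.
#' @return an object of class `tox_cv`: `fold_rates`, `mean_rate`,
#'   `fold_assignment`, `confusions` (per fold), `pooled` (overall
#'   confusion), and `params` (including the denominator policy).
#' @export
cross_validate <- function(records, fingerprints = NULL, k = 5L, seed = 1L,
                           min_support = 0.05, min_confidence = 0.75,
                           max_len = 5L, max_distance = 15L,
                           surrogate = FALSE, count_all = FALSE) {
  stopifnot(is.data.frame(records),
            all(c("id", "smiles", "lc50") %in% names(records)))
  if (!"category" %in% names(records)) {
    records$category <- ghs_category(records$lc50)
  }
  if (is.null(fingerprints)) {
    fingerprints <- fingerprint_all(
      stats::setNames(records$smiles, records$id), max_distance = max_distance)
  }
  fold <- kfold_split(records$id, records$category, k = k, seed = seed)

  fold_rates <- rep(NA_real_, k)
  confusions <- vector("list", k)
  truth_all <- character(0); pred_all <- character(0)
  for (f in seq_len(k)) {
    test_ids <- names(fold)[fold == f]
    train <- records[!records$id %in% test_ids, , drop = FALSE]
    txns <- build_transactions(train, fingerprints)
    itemsets <- frequent_itemsets(txns, min_support = min_support,
                                  max_len = max_len + 1L)
    ruleset <- generate_rules(itemsets, min_confidence = min_confidence)
    train_pred <- stats::setNames(rep(NA_character_, nrow(train)), train$id)
    if (surrogate) {
      for (id in train$id) {
        hit <- predict_by_rules(fingerprints[[id]], ruleset)
        if (!is.null(hit)) train_pred[[id]] <- hit$category
      }
    }
    preds <- vapply(test_ids, function(id) {
      p <- predict_chemical(fingerprints[[id]], ruleset,
                            fingerprints[train$id], train_pred,
                            surrogate = surrogate)
      c(p$category, p$mode)
    }, character(2))
    category <- preds[1L, ]; mode <- preds[2L, ]
    truth <- records$category[match(test_ids, records$id)]
    confusions[[f]] <- confusion_matrix(truth, category)
    if (nrow(ruleset$rules) == 0L) {
      warning(sprintf("fold %d: training set yields no rules; rate undefined", f))
    } else {
      if (count_all) {
        fold_rates[[f]] <- mean(category == truth)
      } else {
        cls <- mode == "rule"
        fold_rates[[f]] <- if (any(cls)) mean(category[cls] == truth[cls])
                           else NA_real_
        if (!any(cls)) {
          warning(sprintf("fold %d: no test chemical rule-classified; rate undefined", f))
        }
      }
    }
    truth_all <- c(truth_all, truth); pred_all <- c(pred_all, category)
  }

  structure(list(
    fold_rates = fold_rates,
    mean_rate = mean(fold_rates, na.rm = TRUE),
    fold_assignment = fold,
    confusions = confusions,
    pooled = confusion_matrix(truth_all, pred_all),
    params = list(k = k, seed = seed, min_support = min_support,
                  min_confidence = min_confidence, max_len = max_len,
                  max_distance = max_distance, surrogate = surrogate,
                  denominator = if (count_all) "all" else "rule-classified")
  ), class = "tox_cv")
}

#' @export
print.tox_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d, %s denominator)\n",
              x$params$k, x$params$seed, x$params$denominator))
  cat("  fold rates:",
      paste(ifelse(is.na(x$fold_rates), "NA",
                   sprintf("%.2f", x$fold_rates)), collapse = " "), "\n")
  cat(sprintf("  mean rate: %.3f\n", x$mean_rate))
  invisible(x)
}
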