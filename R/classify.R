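# Rule-based GHS prediction with Tanimoto nearest-neighbour surrogate
# fallback.

#' Predict a category by rule match
#'
#' Among rules whose whole antecedent is contained in the fingerprint, the
#' winner is chosen by highest confidence, ties by highest lift, ties by the
#' more hazardous category (lower category number), ties by the total rule
#' order used by [top_rules()] (smaller antecedent, then lexicographic).
#' Returns `NULL` when no rule matches.
#'
#' @param fp an `atompair_fp` (or character vector of feature keys).
#' @param ruleset a `tox_ruleset`.
#' @return `NULL`, or a list with `category`, `rule` (one-row data frame),
#'   `confidence`, `lift`.
#' @export
predict_by_rules <- function(fp, ruleset) {
  stopifnot(inherits(ruleset, "tox_ruleset"))
  feats <- if (inherits(fp, "atompair_fp")) fp$features else as.character(fp)
  rules <- ruleset$rules
  if (nrow(rules) == 0L) return(NULL)
  hit <- vapply(rules$lhs, function(l) all(l %in% feats), logical(1))
  if (!any(hit)) return(NULL)
  r <- rules[hit, , drop = FALSE]
  cat_rank <- match(r$rhs, GHS_CATEGORIES)
  r <- r[order(-r$confidence, -r$lift, cat_rank, r$size, r$lhs_key), ,
         drop = FALSE]
  best <- r[1L, , drop = FALSE]
  rownames(best) <- NULL
  list(category = best$rhs, rule = best,
       confidence = best$confidence, lift = best$lift)
}

#' Tanimoto nearest neighbour among training fingerprints
#'
#' Returns the training id minimising the Tanimoto distance to the query.
#' Pairs for which the similarity is undefined (both fingerprints empty) are
#' skipped.  Ties are broken by larger feature-set intersection, then by
#' lexicographic id.
#'
#' @param fp query `atompair_fp` (or character vector of features).
#' @param training named list of `atompair_fp` (or of character vectors).
#' @return list with `id` and `distance`.
#' @export
nearest_neighbor <- function(fp, training) {
  feats <- unique(if (inherits(fp, "atompair_fp")) fp$features else as.character(fp))
  if (length(training) == 0L) stop("empty training set", call. = FALSE)
  ids <- names(training)
  if (is.null(ids)) stop("training fingerprints must be named by id", call. = FALSE)
  dist <- rep(NA_real_, length(training))
  inter <- rep(-1L, length(training))
  for (i in seq_along(training)) {
    tf <- training[[i]]
    tf <- unique(if (inherits(tf, "atompair_fp")) tf$features else as.character(tf))
    un <- length(union(feats, tf))
    if (un == 0L) next  # undefined pair
    ix <- length(intersect(feats, tf))
    dist[[i]] <- 1 - ix / un
    inter[[i]] <- ix
  }
  if (all(is.na(dist))) {
    stop("Tanimoto distance undefined against every training chemical",
         call. = FALSE)
  }
  ord <- order(dist, -inter, ids, na.last = TRUE)
  best <- ord[[1L]]
  list(id = ids[[best]], distance = dist[[best]])
}

#' Predict the GHS category of one fingerprint under a trained model
#'
#' Rule-based prediction when any rule antecedent is contained in the
#' fingerprint; otherwise the surrogate: the Apriori-predicted (not ground
#' truth) category of the Tanimoto-nearest training chemical that itself has
#' a rule-based prediction.  Queries with an empty fingerprint, or models in
#' which no training chemical is rule-covered, yield `"unclassifiable"`.
#'
#' @param fp query `atompair_fp`.
#' @param ruleset a `tox_ruleset`.
#' @param training named list of training `atompair_fp`.
#' @param train_rule_pred named character: rule-based predicted category per
#'   rule-covered training id (others absent or `NA`).
#' @param surrogate use the nearest-neighbour fallback (default `TRUE`);
#'   when `FALSE`, unmatched queries are `"unclassifiable"`.
#' @return list with `id`, `category` (or `"unclassifiable"`), `mode`
#'   (`"rule"`, `"surrogate"` or `"none"`), and the supporting evidence
#'   (`rule`, `confidence`, `lift` in rule mode; `neighbor`, `distance` in
#'   surrogate mode).
#' @export
predict_chemical <- function(fp, ruleset, training = NULL,
                             train_rule_pred = NULL, surrogate = TRUE) {
  id <- if (inherits(fp, "atompair_fp")) fp$id else NA_character_
  hit <- predict_by_rules(fp, ruleset)
  if (!is.null(hit)) {
    return(list(id = id, category = hit$category, mode = "rule",
                rule = hit$rule, confidence = hit$confidence,
                lift = hit$lift, neighbor = NA_character_,
                distance = NA_real_))
  }
  none <- list(id = id, category = "unclassifiable", mode = "none",
               rule = NULL, confidence = NA_real_, lift = NA_real_,
               neighbor = NA_character_, distance = NA_real_)
  if (!surrogate || is.null(training)) return(none)
  covered <- names(train_rule_pred)[!is.na(train_rule_pred)]
  covered <- intersect(covered, names(training))
  if (length(covered) == 0L) return(none)
  feats <- if (inherits(fp, "atompair_fp")) fp$features else as.character(fp)
  if (length(feats) == 0L) return(none)
  nn <- nearest_neighbor(fp, training[covered])
  list(id = id, category = unname(train_rule_pred[[nn$id]]),
       mode = "surrogate", rule = NULL, confidence = NA_real_,
       lift = NA_real_, neighbor = nn$id, distance = nn$distance)
}
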