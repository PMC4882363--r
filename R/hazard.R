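# GHS acute aquatic toxicity discretisation and hazard-table input.

GHS_CATEGORIES <- c("CAT1", "CAT2", "CAT3", "CAT4")

#' GHS acute aquatic toxicity category from a 96-h fish LC50
#'
#' Discretises an LC50 (mg/L, 96-h fathead minnow) into the three GHS acute
#' categories plus a fourth catch-all for LC50 above 100 mg/L:
#' CAT1 for LC50 <= 1, CAT2 for 1 < LC50 <= 10, CAT3 for 10 < LC50 <= 100,
#' CAT4 above 100.  Boundaries follow the official GHS convention of
#' inclusive upper bounds, so exactly 1.0 mg/L is the more hazardous CAT1.
#'
#' @param lc50 numeric vector of LC50 values in mg/L; must be finite and
#'   positive.
#' @return a character vector of `"CAT1"`..`"CAT4"`.
#' @examples
#' ghs_category(c(0.5, 10, 100, 150))
#' @export
ghs_category <- function(lc50) {
  if (!is.numeric(lc50) || any(!is.finite(lc50)) || any(lc50 <= 0)) {
    stop("lc50 must be finite and > 0 (mg/L)", call. = FALSE)
  }
  cut(lc50, breaks = c(0, 1, 10, 100, Inf), labels = GHS_CATEGORIES,
      right = TRUE) |> as.character()
}

#' Read a hazard table (id, SMILES, LC50) from CSV
#'
#' Expects a comma-separated UTF-8 file with header columns `id`, `smiles`
#' and `lc50_mg_per_L` (`.` decimal point, no unit conversion).  The GHS
#' category is derived for every row.
#'
#' @param path CSV file path.
#' @return a data frame with columns `id`, `smiles`, `lc50`, `category`,
#'   rows in file order.
#' @export
read_hazard_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("id", "smiles", "lc50_mg_per_L")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("hazard CSV %s is missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0L) stop(sprintf("hazard CSV %s has no rows", path),
                           call. = FALSE)
  dup <- df$id[duplicated(df$id)]
  if (length(dup) > 0L) {
    stop(sprintf("duplicate chemical id(s) in %s: %s", path,
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  lc50 <- suppressWarnings(as.numeric(df$lc50_mg_per_L))
  bad <- which(is.na(lc50) | !is.finite(lc50) | lc50 <= 0)
  if (length(bad) > 0L) {
    stop(sprintf("invalid LC50 in %s at row %d (id '%s'): '%s'",
                 path, bad[1L], df$id[bad[1L]], df$lc50_mg_per_L[bad[1L]]),
         call. = FALSE)
  }
  data.frame(id = df$id, smiles = df$smiles, lc50 = lc50,
             category = ghs_category(lc50), stringsAsFactors = FALSE)
}

#' Build a hazard table from vectors
#'
#' Convenience constructor performing the same validation as
#' [read_hazard_csv()].
#'
#' @param id character ids (unique).
#' @param smiles SMILES strings.
#' @param lc50 LC50 values, mg/L.
#' @return data frame with `id`, `smiles`, `lc50`, `category`.
#' @export
hazard_records <- function(id, smiles, lc50) {
  stopifnot(length(id) == length(smiles), length(id) == length(lc50))
  if (anyDuplicated(id)) stop("chemical ids must be unique", call. = FALSE)
  data.frame(id = as.character(id), smiles = as.character(smiles),
             lc50 = as.numeric(lc50), category = ghs_category(lc50),
             stringsAsFactors = FALSE)
}
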