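## Check-anchored drought-tolerance categorization: accession yields are
## binned against the yields of replicated reference checks of known
## behavior.  Band boundaries, from the top: the best tolerant check, a
## designated tolerant "upper anchor" (the weakest tolerant check), and a
## designated susceptible "lower anchor".

.DM_CATEGORIES <- c("high-yielding drought-tolerant",
                    "moderately resistant",
                    "moderately susceptible",
                    "highly drought-susceptible")

#' Configure the reference checks anchoring tolerance categories
#'
#' @param tolerant Ordered character vector of drought-tolerant check
#'   names (strongest first by reputation; ordering is informational).
#' @param susceptible Ordered character vector of drought-susceptible
#'   check names.
#' @param upper_anchor Tolerant check whose yield bounds the
#'   moderately-resistant band from below (default: last tolerant check).
#' @param lower_anchor Susceptible check whose yield bounds the
#'   highly-susceptible band from above (default: first susceptible
#'   check).
#' @return Object of class `"check_config"`.
#' @examples
#' check_config()  # the published check set
#' @export
check_config <- function(tolerant = c("Apo", "Norungan", "CO 53",
                                      "Anna (R) 4"),
                         susceptible = c("IR 64", "Jaya", "Pusa 44"),
                         upper_anchor = tolerant[length(tolerant)],
                         lower_anchor = susceptible[1]) {
  if (!length(tolerant) || !length(susceptible))
    stop("both check lists must be non-empty")
  if (length(intersect(tolerant, susceptible)))
    stop("check lists must be disjoint")
  if (!upper_anchor %in% tolerant)
    stop("upper_anchor must be a tolerant check")
  if (!lower_anchor %in% susceptible)
    stop("lower_anchor must be a susceptible check")
  structure(list(tolerant = tolerant, susceptible = susceptible,
                 upper_anchor = upper_anchor, lower_anchor = lower_anchor),
            class = "check_config")
}

#' Classify accessions into drought-tolerance categories by yield
#'
#' Band boundaries are the yield values of the checks in the same data:
#' strictly above every tolerant check -> high-yielding drought-tolerant;
#' down to the upper anchor -> moderately resistant; down to the lower
#' anchor -> moderately susceptible; below the lower anchor -> highly
#' drought-susceptible.  An accession exactly equal to a boundary check
#' takes the better category.
#'
#' @param yields Named numeric vector of yields (BLUEs per environment,
#'   or multi-environment predicted values), names = genotypes, including
#'   every check, or a data.frame with `genotype` and a value column.
#' @param checks A [check_config()].
#' @param environment Label recorded in the output (`"multi"` for
#'   across-environment calls).
#' @param value Value column when `yields` is a data.frame.
#' @return data.frame of class `"tolerance_calls"`: `genotype`, `yield`,
#'   `category` (ordered factor), `is_check`, `environment`.
#' @export
classify <- function(yields, checks = check_config(),
                     environment = "multi", value = "predicted") {
  stopifnot(inherits(checks, "check_config"))
  if (is.data.frame(yields)) {
    if (!all(c("genotype", value) %in% names(yields)))
      stop("data.frame input needs `genotype` and `", value, "` columns")
    yields <- stats::setNames(yields[[value]], yields$genotype)
  }
  all_checks <- c(checks$tolerant, checks$susceptible)
  missing <- setdiff(all_checks, names(yields))
  if (length(missing))
    stop("missing check value(s): ", paste(missing, collapse = ", "))

  top <- max(yields[checks$tolerant])
  upper <- yields[[checks$upper_anchor]]
  lower <- yields[[checks$lower_anchor]]

  cat_of <- function(v) ifelse(
    v >= top, .DM_CATEGORIES[1],
    ifelse(v >= upper, .DM_CATEGORIES[2],
           ifelse(v >= lower, .DM_CATEGORIES[3], .DM_CATEGORIES[4])))
  out <- data.frame(genotype = names(yields), yield = unname(yields),
                    category = factor(cat_of(unname(yields)),
                                      levels = .DM_CATEGORIES),
                    is_check = names(yields) %in% all_checks,
                    environment = environment)
  ## sanity: do the checks themselves bin consistently with their labels?
  tol_cat <- out$category[match(checks$tolerant, out$genotype)]
  sus_cat <- out$category[match(checks$susceptible, out$genotype)]
  if (any(as.integer(tol_cat) > 2L) || any(as.integer(sus_cat) < 3L))
    message("note: observed check ranking inconsistent with tolerance ",
            "labels in ", environment,
            " (a tolerant check fell below the anchor band, or a ",
            "susceptible check above it)")
  structure(out, class = c("tolerance_calls", "data.frame"))
}

#' Per-category counts and panel percentages
#'
#' Checks are excluded from both numerator and denominator; percentages
#' are of the non-check panel, reported to 2 decimals.
#'
#' @param calls A `"tolerance_calls"` data.frame from [classify()].
#' @return data.frame `category`, `count`, `percent`.
#' @examples
#' # 37 tolerant accessions of a 500-accession panel -> 7.40%
#' @export
category_summary <- function(calls) {
  stopifnot(is.data.frame(calls), nrow(calls) > 0)
  tests <- calls[!calls$is_check, , drop = FALSE]
  n <- nrow(tests)
  counts <- table(factor(tests$category, levels = .DM_CATEGORIES))
  data.frame(category = names(counts), count = as.integer(counts),
             percent = round(100 * as.integer(counts) / n, 2),
             row.names = NULL)
}

#' Accessions called tolerant in every environment
#'
#' @param calls_list List of `"tolerance_calls"` (one per environment).
#' @return Sorted character vector: the intersection of the
#'   high-yielding drought-tolerant category across environments,
#'   checks excluded.
#' @export
consistent_tolerant <- function(calls_list) {
  stopifnot(is.list(calls_list), length(calls_list) >= 2L)
  sets <- lapply(calls_list, function(cl)
    cl$genotype[!cl$is_check & cl$category == .DM_CATEGORIES[1]])
  sort(Reduce(intersect, sets))
}
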