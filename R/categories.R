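#' The six-category behavioural response
#'
#' Scan-sampling observations are collapsed onto six behaviour categories for
#' multinomial modelling: active nonhelping, eating, food carrying, nest
#' building, resting and working. Resting is the reference category of the
#' multinomial logit (its linear predictor is fixed at zero), so correlations
#' between resting and nonresting behaviours are never estimated. Food
#' carrying, nest building and working are the cooperative (helping)
#' categories; the task-specialization test concerns trade-offs among these.
#'
#' @return `behaviour_categories()`: character vector of the six category
#'   labels in canonical order.
#' @export
behaviour_categories <- function() {
  c("active_nonhelping", "eat", "food_carry", "nest_building", "rest", "work")
}

#' @rdname behaviour_categories
#' @return `reference_category()`: the reference label (`"rest"`).
#' @export
reference_category <- function() "rest"

#' @rdname behaviour_categories
#' @return `nonreference_categories()`: the five modelled (non-reference)
#'   labels, in the order used for model parameters.
#' @export
nonreference_categories <- function() {
  setdiff(behaviour_categories(), reference_category())
}

#' @rdname behaviour_categories
#' @return `cooperative_categories()`: the three helping categories.
#' @export
cooperative_categories <- function() c("food_carry", "nest_building", "work")

#' Collapse a raw ethogram onto the six modelled categories
#'
#' Observation protocols typically distinguish many raw behaviours (the study
#' design this package emulates used a 16-behaviour ethogram); the model works
#' on six collapsed categories. The mapping is user-supplied and must be a
#' surjection onto the six categories.
#'
#' @param labels character vector of raw behaviour labels to collapse.
#' @param mapping either a named character vector (`names` = raw labels,
#'   values = categories) or a data frame with columns `raw_label`,
#'   `category`.
#' @return character vector of collapsed category labels, same length as
#'   `labels`.
#' @export
collapse_ethogram <- function(labels, mapping) {
  if (is.data.frame(mapping)) {
    stopifnot(all(c("raw_label", "category") %in% names(mapping)))
    mapping <- stats::setNames(as.character(mapping$category),
                               as.character(mapping$raw_label))
  }
  cats <- behaviour_categories()
  bad <- setdiff(unique(mapping), cats)
  if (length(bad) > 0)
    stop("ethogram mapping targets unknown categories: ",
         paste(bad, collapse = ", "))
  missing_cat <- setdiff(cats, unique(mapping))
  if (length(missing_cat) > 0)
    stop("ethogram mapping is not surjective; no raw label maps to: ",
         paste(missing_cat, collapse = ", "))
  unmapped <- setdiff(unique(labels), names(mapping))
  if (length(unmapped) > 0)
    stop("unmapped raw behaviour label(s): ", paste(unmapped, collapse = ", "))
  unname(mapping[labels])
}

#' Read an ethogram mapping file
#'
#' @param path CSV file with header `raw_label,category`.
#' @return named character vector suitable for [collapse_ethogram()].
#' @export
read_ethogram <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("raw_label", "category") %in% names(df)))
    stop("ethogram file must have columns raw_label,category: ", path)
  stats::setNames(df$category, df$raw_label)
}
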