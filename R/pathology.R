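# The five IASLC/ATS/ERS invasive growth patterns, and the fixed
# aggressiveness order used for deterministic tie-breaking (most aggressive
# first): solid > micropapillary > papillary > acinar > lepidic.
SUBTYPES <- c("lepidic", "acinar", "papillary", "micropapillary", "solid")
AGGRESSIVENESS <- c("solid", "micropapillary", "papillary", "acinar", "lepidic")

SUBTYPE_GROUPS <- c("ONE", "TWO", "THREE_OR_FOUR")

#' Validate and repair a histologic subtype composition
#'
#' Comprehensive histologic subtyping reports each growth pattern to the
#' nearest 5\%, summing to 100\% across the five subtypes. This constructor
#' renormalizes raw percentages to sum 100, rounds onto the 5\% grid using
#' largest-remainder allocation of the 20 five-percent units, and stores an
#' optional fibrosis percentage outside the subtype simplex. Remainder ties
#' are broken by the larger raw percentage, then by the fixed aggressiveness
#' order.
#'
#' @param raw named numeric of percentages; names a subset of the five
#'   subtypes (missing subtypes count as 0).
#' @param fibrosis optional fibrosis percentage (kept, not renormalized).
#' @return a \linkS4class{SubtypeComposition}.
#' @examples
#' validateComposition(c(acinar = 47, papillary = 53))  # -> 45 / 55
#' @export
validateComposition <- function(raw, fibrosis = NA_real_) {
  raw <- unlist(raw)
  if (length(raw) == 0L)
    stop("invalid composition: no subtype percentages supplied")
  if (is.null(names(raw)) || !all(names(raw) %in% c(SUBTYPES, "fibrosis")))
    stop("invalid composition: names must be among ",
         paste(SUBTYPES, collapse = ", "), " (+ fibrosis)")
  if ("fibrosis" %in% names(raw)) {
    if (is.na(fibrosis)) fibrosis <- unname(raw[["fibrosis"]])
    raw <- raw[names(raw) != "fibrosis"]
  }
  p <- stats::setNames(numeric(length(SUBTYPES)), SUBTYPES)
  p[names(raw)] <- as.numeric(raw)
  if (any(!is.finite(p)) || any(p < 0))
    stop("invalid composition: percentages must be finite and non-negative")
  if (sum(p) <= 0)
    stop("invalid composition: subtype percentages sum to 0")
  units <- p * (100 / sum(p)) / 5          # target in 5%-units, total 20
  fl <- floor(units)
  rem <- units - fl
  short <- 20L - as.integer(sum(fl))
  if (short > 0L) {
    ord <- order(-rem, -p, match(SUBTYPES, AGGRESSIVENESS))
    fl[ord[seq_len(short)]] <- fl[ord[seq_len(short)]] + 1
  }
  new("SubtypeComposition", percent = fl * 5,
      fibrosis = as.numeric(fibrosis))
}

#' Default hazard-ratio-derived subtype weights
#'
#' The pathologic heterogeneity index weights each subtype by its prognostic
#' hazard; the defaults shipped here are package defaults ordered by the
#' established subtype aggressiveness (lepidic indolent; acinar/papillary
#' intermediate; micropapillary/solid aggressive), not estimates from any
#' cohort. Any published disease-free-survival hazard-ratio set can be
#' supplied in their place wherever a weights argument is accepted.
#'
#' @return named numeric(5) of non-negative weights.
#' @export
defaultSubtypeWeights <- function() {
  c(lepidic = 0, acinar = 1, papillary = 1, micropapillary = 2, solid = 2)
}

#' Pathologic heterogeneity index
#'
#' The hazard-weighted mixture score index = sum over subtypes s of
#' w_s * percent_s / 100: a dimensionless summary of how much of the tumor
#' is made of prognostically adverse growth patterns, linear in the
#' proportions and deterministic.
#'
#' @param comp a \linkS4class{SubtypeComposition}.
#' @param weights named non-negative weights covering every subtype present
#'   in \code{comp} (default \code{\link{defaultSubtypeWeights}}).
#' @return numeric(1) index value.
#' @export
heterogeneityIndex <- function(comp, weights = defaultSubtypeWeights()) {
  stopifnot(is(comp, "SubtypeComposition"))
  present <- names(comp@percent)[comp@percent > 0]
  if (!all(present %in% names(weights)))
    stop("missing weight for subtype(s): ",
         paste(setdiff(present, names(weights)), collapse = ", "))
  w <- weights[present]
  if (any(!is.finite(w)) || any(w < 0))
    stop("subtype weights must be finite and non-negative")
  sum(w * comp@percent[present] / 100)
}

#' Subtype count and heterogeneity group
#'
#' Counts the strictly positive subtypes and assigns the three-level
#' grouping used for group comparisons: ONE (single pattern), TWO, or
#' THREE_OR_FOUR (three or more patterns).
#'
#' @param comp a \linkS4class{SubtypeComposition}.
#' @return list with \code{nSubtypes} (integer) and \code{group} (factor
#'   with levels ONE, TWO, THREE_OR_FOUR).
#' @export
subtypeCountAndGroup <- function(comp) {
  stopifnot(is(comp, "SubtypeComposition"))
  n <- sum(comp@percent > 0)
  grp <- if (n == 1L) "ONE" else if (n == 2L) "TWO" else "THREE_OR_FOUR"
  list(nSubtypes = as.integer(n),
       group = factor(grp, levels = SUBTYPE_GROUPS))
}

#' Predominant histologic subtype
#'
#' The growth pattern with the largest percentage; ties are broken by the
#' fixed aggressiveness order solid > micropapillary > papillary > acinar >
#' lepidic.
#'
#' @param comp a \linkS4class{SubtypeComposition}.
#' @return character(1) subtype name.
#' @export
predominantSubtype <- function(comp) {
  stopifnot(is(comp, "SubtypeComposition"))
  p <- comp@percent[AGGRESSIVENESS]
  names(p)[which.max(p)]
}

#' Read a pathology table
#'
#' CSV with columns tumor_id, lepidic, acinar, papillary, micropapillary,
#' solid and optionally fibrosis plus exclusion-flag columns; percentages
#' are integers.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
readPathologyTable <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("malformed pathology CSV '", path, "': ",
                             conditionMessage(e)))
  need <- c("tumor_id", SUBTYPES)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("pathology CSV is missing column(s): ", paste(miss, collapse = ", "))
  df
}

# Build SubtypeComposition objects for each row of a pathology data.frame.
compositionsFromTable <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    fib <- if ("fibrosis" %in% names(df)) df$fibrosis[i] else NA_real_
    validateComposition(unlist(df[i, SUBTYPES]), fibrosis = fib)
  })
}
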