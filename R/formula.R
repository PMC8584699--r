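#' Parse a Hill-style elemental formula
#'
#' Splits a formula such as `"C6H12O6"` into element counts. An element
#' symbol is an upper-case letter followed by lower-case letters;
#' pseudo-elements used by curated reaction databases (e.g. `"R"`, `"X"`)
#' are accepted as opaque symbols. An omitted count means 1. Counts may
#' be non-negative decimals (average formulas in semi-automated
#' reconstructions use them), although integers are the common case.
#'
#' @param formula formula string.
#' @return named numeric vector, element symbol -> count. Repeated
#'   symbols are summed.
#' @examples
#' parse_formula("C6H12O6")
#' parse_formula("CHO2R")
#' @export
parse_formula <- function(formula) {
  if (length(formula) != 1L || is.na(formula) || !nzchar(formula)) {
    stop("parse_formula: formula must be a single non-empty string")
  }
  m <- gregexpr("[A-Z][a-z]*([0-9]+(\\.[0-9]+)?)?", formula)[[1L]]
  tokens <- regmatches(formula, list(m))[[1L]]
  if (sum(attr(m, "match.length")) != nchar(formula)) {
    stop("parse_formula: unparseable formula '", formula, "'")
  }
  sym <- sub("[0-9.]+$", "", tokens)
  cnt <- suppressWarnings(as.numeric(sub("^[A-Za-z]+", "", tokens)))
  cnt[is.na(cnt)] <- 1
  out <- tapply(cnt, sym, sum)
  stats::setNames(as.numeric(out), names(out))
}

#' Check the mass (and charge) balance of a reaction
#'
#' A reaction is `"balanced"` when, for every element and for charge,
#' the stoichiometry-weighted sums over all participants are zero;
#' `"imbalanced"` when some element or the charge does not cancel; and
#' `"undetermined"` when any participant lacks a formula. When any
#' participant lacks a charge the charge test is skipped and the verdict
#' rests on the elements alone.
#'
#' Exchange and biomass reactions are by convention not mass balanced
#' and should not be passed here (curation removes them by other rules).
#'
#' @param stoich named numeric vector, metabolite id -> coefficient
#'   (negative = consumed), e.g. from [reaction_stoichiometry()].
#' @param catalog data frame with columns `id`, `formula`, `charge`
#'   covering (at least) the participating metabolites.
#' @param tol numeric tolerance on the per-element sums.
#' @return one of `"balanced"`, `"imbalanced"`, `"undetermined"`.
#' @examples
#' cat <- data.frame(id = c("glc", "lac"),
#'                   formula = c("C6H12O6", "C3H6O3"), charge = c(0, 0))
#' check_mass_balance(c(glc = -1, lac = 2), cat)
#' @export
check_mass_balance <- function(stoich, catalog, tol = 1e-9) {
  idx <- match(names(stoich), catalog$id)
  if (anyNA(idx)) {
    stop("check_mass_balance: metabolite(s) absent from catalog: ",
         paste(names(stoich)[is.na(idx)], collapse = ", "))
  }
  formulas <- catalog$formula[idx]
  if (any(is.na(formulas) | !nzchar(formulas))) return("undetermined")
  elems <- lapply(formulas, parse_formula)
  all_sym <- unique(unlist(lapply(elems, names)))
  bal <- numeric(length(all_sym)); names(bal) <- all_sym
  for (k in seq_along(stoich)) {
    e <- elems[[k]]
    bal[names(e)] <- bal[names(e)] + stoich[[k]] * e
  }
  if (any(abs(bal) > tol)) return("imbalanced")
  charges <- catalog$charge[idx]
  if (!any(is.na(charges))) {
    if (abs(sum(stoich * charges)) > tol) return("imbalanced")
  }
  "balanced"
}
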