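#' Build a coefficient table for a fixed logistic risk model
#'
#' A coefficient table is the frozen logistic model a deployed risk score
#' applies: an intercept plus one log-odds coefficient per binary covariate,
#' each labelled with one of the five CAN covariate categories (demographic,
#' diagnostic, laboratory_vitals, pharmacy, utilization). The odds ratio of a
#' covariate is `exp(coefficient)`.
#'
#' @param intercept log-odds intercept.
#' @param coefficients named numeric vector of per-covariate log-odds
#'   coefficients; names are covariate (panel column) names.
#' @param categories character vector of category labels, recycled against
#'   `coefficients`; entries must be among the five categories or `NA`.
#' @param groups optional character vector marking mutually exclusive dummy
#'   groups (levels of one categorical variable); `NA` for independent
#'   covariates. Used by [retrain()] to drop sibling levels together.
#' @return A data.frame of class `coefficient_table` with columns `covariate`,
#'   `category`, `coefficient`, `group`; the intercept is the `"(Intercept)"`
#'   row.
#' @seealso [ct_intercept()], [ct_beta()], [read_coefficients()]
#' @export
coefficient_table <- function(intercept, coefficients, categories = NA_character_,
                              groups = NA_character_) {
  if (length(intercept) != 1L || !is.finite(intercept))
    stop("intercept must be a single finite number")
  nm <- names(coefficients)
  if (length(coefficients) && (is.null(nm) || anyNA(nm) || any(nm == "") ||
                               anyDuplicated(nm)))
    stop("coefficients must have unique non-empty names")
  nm <- as.character(nm)
  if ("(Intercept)" %in% nm)
    stop("'(Intercept)' is reserved; pass the intercept separately")
  if (!all(is.finite(coefficients)))
    stop("coefficients must be finite")
  categories <- if (length(coefficients))
    rep_len(as.character(categories), length(coefficients)) else character(0)
  bad <- !is.na(categories) & !(categories %in% can_categories)
  if (any(bad))
    stop("unknown categories: ", paste(unique(categories[bad]), collapse = ", "))
  groups <- if (length(coefficients))
    rep_len(as.character(groups), length(coefficients)) else character(0)
  out <- data.frame(
    covariate   = c("(Intercept)", nm),
    category    = c(NA_character_, categories),
    coefficient = c(intercept, unname(coefficients)),
    group       = c(NA_character_, groups),
    stringsAsFactors = FALSE
  )
  class(out) <- c("coefficient_table", "data.frame")
  out
}

#' @rdname coefficient_table
#' @param x a `coefficient_table`.
#' @export
ct_intercept <- function(x) {
  x$coefficient[x$covariate == "(Intercept)"]
}

#' @rdname coefficient_table
#' @export
ct_beta <- function(x) {
  keep <- x$covariate != "(Intercept)"
  setNames(x$coefficient[keep], x$covariate[keep])
}

as_coefficient_table <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("covariate", "coefficient") %in% names(x)),
            "(Intercept)" %in% x$covariate)
  if (is.null(x$category)) x$category <- NA_character_
  if (is.null(x$group)) x$group <- NA_character_
  keep <- x$covariate != "(Intercept)"
  coefficient_table(x$coefficient[!keep][1],
                    setNames(x$coefficient[keep], x$covariate[keep]),
                    x$category[keep], x$group[keep])
}
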