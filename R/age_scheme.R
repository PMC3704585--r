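#' Age-class schemes for stratified surveillance counts
#'
#' An age scheme is an ordered set of contiguous, non-overlapping age
#' classes with bounds in months (lower inclusive, upper exclusive) and a
#' midpoint in years. Exactly the last class may be open-ended (upper bound
#' `NA`); its midpoint is supplied rather than computed.
#'
#' @param label character vector of class labels.
#' @param lower,upper integer bounds in months; `upper` is `NA` for the
#'   open-ended last class.
#' @param midpoint class midpoints in years. For bounded classes this must
#'   equal `(lower + upper) / 2 / 12`.
#' @return A data frame of class `age_scheme` with columns `label`,
#'   `lower`, `upper`, `midpoint`.
#' @export
age_scheme <- function(label, lower, upper, midpoint) {
  stopifnot(length(label) == length(lower),
            length(lower) == length(upper),
            length(upper) == length(midpoint))
  n <- length(label)
  if (n < 1L) stop("an age scheme needs at least one class")
  if (anyDuplicated(label)) stop("age-class labels must be unique")
  open <- is.na(upper)
  if (any(open[-n])) stop("only the last class may be open-ended")
  if (any(lower[!open] >= upper[!open]))
    stop("lower bound must be below upper bound for bounded classes")
  if (n > 1L) {
    if (any(lower[-1L] != upper[-n]))
      stop("classes must be contiguous: each lower bound must equal the previous upper bound")
    if (any(diff(midpoint) <= 0))
      stop("midpoints must be strictly increasing")
  }
  bounded_mid <- (lower[!open] + upper[!open]) / 2 / 12
  if (any(abs(midpoint[!open] - bounded_mid) > 1e-9))
    stop("bounded-class midpoints must equal the interval midpoint in years")
  out <- data.frame(label = as.character(label),
                    lower = as.integer(lower),
                    upper = as.integer(upper),
                    midpoint = as.numeric(midpoint),
                    stringsAsFactors = FALSE)
  class(out) <- c("age_scheme", "data.frame")
  out
}

#' @export
print.age_scheme <- function(x, ...) {
  cat(sprintf("Age scheme: %d classes, %s months to %s\n", nrow(x),
              x$lower[1L],
              if (is.na(x$upper[nrow(x)])) "open" else x$upper[nrow(x)]))
  print.data.frame(x, ...)
  invisible(x)
}

#' Fine 19-class age scheme for Kawasaki disease surveillance
#'
#' Builds the 19-class stratification used by the nationwide KD
#' surveillance: eight 3-month classes below 2 years, two 6-month classes
#' in the second year... through single-year classes up to 9 years, and an
#' open class at 10 years and above. The open class has no natural
#' midpoint; 10.5 years is the primary choice, with 15 years used as a
#' sensitivity value.
#'
#' @param oldest_midpoint midpoint in years assigned to the open (>= 10 y)
#'   class; must exceed 10.
#' @return An [age_scheme] with 19 classes.
#' @examples
#' fine_age_scheme()          # open-class midpoint 10.5 y
#' fine_age_scheme(15)        # sensitivity variant
#' @export
fine_age_scheme <- function(oldest_midpoint = 10.5) {
  if (!is.numeric(oldest_midpoint) || length(oldest_midpoint) != 1L ||
      oldest_midpoint <= 10)
    stop("oldest_midpoint must be a single number greater than 10 years")
  lower <- c(0L, 3L, 6L, 9L, 12L, 15L, 18L, 21L, 24L, 30L,
             36L, 42L, 48L, 60L, 72L, 84L, 96L, 108L, 120L)
  upper <- c(lower[-1L], NA)
  label <- c("0-2m", "3-5m", "6-8m", "9-11m", "12-14m", "15-17m",
             "18-20m", "21-23m", "2y-2y5m", "2y6m-2y11m", "3y-3y5m",
             "3y6m-3y11m", "4y-4y11m", "5y-5y11m", "6y-6y11m",
             "7y-7y11m", "8y-8y11m", "9y-9y11m", "10y+")
  mid <- (lower + upper) / 2 / 12
  mid[length(mid)] <- oldest_midpoint
  age_scheme(label, lower, upper, mid)
}

#' Coarse 11-class age scheme (census resolution)
#'
#' Census population data resolves age only to whole years, so the
#' 19-class case stratification is aggregated to 11 classes: under 1 year,
#' ten single-year classes, with the last (>= 10 y) open.
#'
#' @inheritParams fine_age_scheme
#' @return An [age_scheme] with 11 classes.
#' @export
coarse_age_scheme <- function(oldest_midpoint = 10.5) {
  if (!is.numeric(oldest_midpoint) || length(oldest_midpoint) != 1L ||
      oldest_midpoint <= 10)
    stop("oldest_midpoint must be a single number greater than 10 years")
  lower <- seq(0L, 120L, by = 12L)
  upper <- c(lower[-1L], NA)
  label <- c("<1y", paste0(1:9, "y"), "10y+")
  mid <- (lower + upper) / 2 / 12
  mid[length(mid)] <- oldest_midpoint
  age_scheme(label, lower, upper, mid)
}

#' Aggregate a fine-scheme case panel to the coarse scheme
#'
#' Sums fine age-class counts into the whole-year classes of
#' [coarse_age_scheme()]. Total counts per (region, year) are conserved
#' exactly.
#'
#' @param cases case panel data frame with columns `region`, `year`,
#'   `age_class`, `count`, keyed on `fine`.
#' @param fine the fine [age_scheme] the panel is keyed on.
#' @param oldest_midpoint midpoint for the coarse open class; defaults to
#'   the fine scheme's open-class midpoint.
#' @return A list with elements `scheme` (the coarse [age_scheme]) and
#'   `cases` (the aggregated panel).
#' @export
aggregate_to_coarse <- function(cases, fine = fine_age_scheme(),
                                oldest_midpoint = fine$midpoint[nrow(fine)]) {
  validate_case_panel(cases, fine)
  coarse <- coarse_age_scheme(oldest_midpoint)
  idx <- match(cases$age_class, fine$label)
  coarse_idx <- pmin(fine$lower[idx] %/% 12L, 10L) + 1L
  key <- interaction(cases$region, cases$year, coarse$label[coarse_idx],
                     drop = TRUE, sep = "\r")
  agg <- rowsum(cases$count, key)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  out <- data.frame(region = vapply(parts, `[[`, "", 1L),
                    year = as.integer(vapply(parts, `[[`, "", 2L)),
                    age_class = vapply(parts, `[[`, "", 3L),
                    count = as.vector(agg),
                    stringsAsFactors = FALSE)
  out <- out[order(out$region, out$year, match(out$age_class, coarse$label)), ]
  rownames(out) <- NULL
  list(scheme = coarse, cases = out)
}

#' Validate a case panel against an age scheme
#'
#' Checks column presence, non-negative integer counts, membership of all
#' age-class labels in the scheme, and uniqueness of
#' (region, year, age_class) keys.
#'
#' @inheritParams aggregate_to_coarse
#' @param scheme the [age_scheme] the panel must be keyed on.
#' @return The panel, invisibly, on success.
#' @export
validate_case_panel <- function(cases, scheme) {
  req <- c("region", "year", "age_class", "count")
  miss <- setdiff(req, names(cases))
  if (length(miss))
    stop("case panel is missing columns: ", paste(miss, collapse = ", "))
  if (any(is.na(cases$count)) || any(cases$count < 0))
    stop("case counts must be non-negative")
  bad <- setdiff(unique(cases$age_class), scheme$label)
  if (length(bad))
    stop("unknown age-class labels: ", paste(bad, collapse = ", "))
  if (anyDuplicated(cases[c("region", "year", "age_class")]))
    stop("duplicate (region, year, age_class) keys in case panel")
  invisible(cases)
}

#' Validate a population panel against an age scheme
#'
#' @param pop population panel data frame with columns `region`, `year`,
#'   `age_class`, `population`.
#' @inheritParams validate_case_panel
#' @return The panel, invisibly, on success.
#' @export
validate_population_panel <- function(pop, scheme) {
  req <- c("region", "year", "age_class", "population")
  miss <- setdiff(req, names(pop))
  if (length(miss))
    stop("population panel is missing columns: ", paste(miss, collapse = ", "))
  if (any(is.na(pop$population)) || any(pop$population <= 0))
    stop("populations must be strictly positive")
  bad <- setdiff(unique(pop$age_class), scheme$label)
  if (length(bad))
    stop("unknown age-class labels: ", paste(bad, collapse = ", "))
  if (anyDuplicated(pop[c("region", "year", "age_class")]))
    stop("duplicate (region, year, age_class) keys in population panel")
  invisible(pop)
}

#' Validate a standard population structure
#'
#' The standard structure assigns each age class of a scheme a proportion;
#' proportions must cover the scheme and sum to one.
#'
#' @param standard data frame with columns `age_class`, `proportion`.
#' @inheritParams validate_case_panel
#' @return The standard, invisibly, on success.
#' @export
validate_standard <- function(standard, scheme) {
  req <- c("age_class", "proportion")
  miss <- setdiff(req, names(standard))
  if (length(miss))
    stop("standard structure is missing columns: ", paste(miss, collapse = ", "))
  if (!setequal(standard$age_class, scheme$label))
    stop("standard structure must cover exactly the scheme's age classes")
  if (abs(sum(standard$proportion) - 1) > 1e-9)
    stop("standard proportions must sum to 1")
  if (any(standard$proportion < 0))
    stop("standard proportions must be non-negative")
  invisible(standard)
}
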