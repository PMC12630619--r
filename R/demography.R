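# Mortality-profile models and integer reference populations.
#
# Assemblage demography is summarised at the coarsest level the composition
# test operates on: adult/adolescent females (F), adult/adolescent males (M)
# and unsexed juveniles aged 0-14 (JUV).

#' Age/sex categories used throughout the package
#'
#' The demographic composition of a skeletal assemblage is described by three
#' categories: adult/adolescent females (`F`), adult/adolescent males (`M`),
#' and juveniles aged 0--14 years, which carry no sex (`JUV`).
#'
#' @return Character vector `c("F", "M", "JUV")`.
#' @export
age_sex_categories <- function() c("F", "M", "JUV")

#' Construct a mortality profile
#'
#' A mortality profile is a probability distribution over the three age/sex
#' categories, i.e. the expected proportions of deaths falling into each
#' category in a population. Profiles are the null models of the assemblage
#' composition test: reference populations are built from them and
#' assemblages are drawn from those populations.
#'
#' @param probs Numeric vector of length 3, non-negative, summing to 1
#'   (within `1e-12`), ordered as (F, M, JUV).
#' @param label Character label for the profile.
#' @return An object of class `mortality_profile` with elements `label` and
#'   `probs` (named numeric vector over F, M, JUV).
#' @seealso [profile_from_components()], [profile_from_counts()],
#'   [build_reference_population()]
#' @export
mortality_profile <- function(probs, label = "profile") {
  if (!is.numeric(probs) || length(probs) != 3L || anyNA(probs)) {
    stop("`probs` must be a numeric vector of length 3 with no NAs",
         call. = FALSE)
  }
  if (any(probs < 0) || any(probs > 1)) {
    stop("each probability must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(probs) - 1) > 1e-12) {
    stop("`probs` must sum to 1 (within 1e-12)", call. = FALSE)
  }
  structure(
    list(label = as.character(label)[1L],
         probs = stats::setNames(as.numeric(probs), age_sex_categories())),
    class = "mortality_profile"
  )
}

#' @export
print.mortality_profile <- function(x, ...) {
  cat("Mortality profile:", x$label, "\n")
  print(round(x$probs, 4))
  invisible(x)
}

#' Build a mortality profile from two interpretable components
#'
#' Parameterizes a profile by the fraction of deaths that are juveniles and
#' the sex ratio among adult/adolescent deaths:
#' `probs = ((1 - d) * s, (1 - d) * (1 - s), d)` where `d` is the juvenile
#' death fraction and `s` the adult female share.
#'
#' @param juvenile_death_fraction Real in \[0, 1\]: proportion of deaths aged
#'   0--14.
#' @param adult_sex_ratio Real in \[0, 1\]: proportion of adult/adolescent
#'   deaths that are female.
#' @param label Profile label.
#' @return A [mortality_profile()].
#' @examples
#' profile_from_components(0.5, 0.5)          # (0.25, 0.25, 0.5)
#' profile_from_components(5/12, 3/7, "chag") # Chagyrskaya-like 3:4:5
#' @export
profile_from_components <- function(juvenile_death_fraction, adult_sex_ratio,
                                    label = "profile") {
  d <- juvenile_death_fraction
  s <- adult_sex_ratio
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 0 || d > 1) {
    stop("`juvenile_death_fraction` must be a single value in [0, 1]",
         call. = FALSE)
  }
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s < 0 || s > 1) {
    stop("`adult_sex_ratio` must be a single value in [0, 1]", call. = FALSE)
  }
  mortality_profile(c((1 - d) * s, (1 - d) * (1 - s), d), label = label)
}

#' Build a mortality profile from observed category counts
#'
#' Normalizes the counts of an observed assemblage (e.g. a well-documented
#' reference assemblage) into a profile.
#'
#' @param counts Non-negative integer vector of length 3 over (F, M, JUV);
#'   at least one count must be positive.
#' @param label Profile label.
#' @return A [mortality_profile()].
#' @examples
#' profile_from_counts(c(3, 4, 5))  # (0.25, 1/3, 5/12)
#' @export
profile_from_counts <- function(counts, label = "profile") {
  check_counts3(counts)
  if (sum(counts) <= 0) {
    stop("at least one count must be positive", call. = FALSE)
  }
  mortality_profile(counts / sum(counts), label = label)
}

#' Build an integer reference population from a mortality profile
#'
#' Scales a profile to a population of `N` individuals using
#' largest-remainder (Hamilton) rounding so the integer category counts sum
#' exactly to `N`. Remainder ties are broken in fixed category order
#' F, M, JUV, making the construction deterministic.
#'
#' @param profile A [mortality_profile()].
#' @param N Positive integer population size (default 60, the standard
#'   reference size for the composition test).
#' @return An object of class `reference_population` with elements `counts`
#'   (named integer vector), `N`, and `label`.
#' @examples
#' build_reference_population(profile_from_counts(c(3, 4, 5)), 60)  # 15/20/25
#' @export
build_reference_population <- function(profile, N = 60) {
  stopifnot(inherits(profile, "mortality_profile"))
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N < 1 ||
      N != round(N)) {
    stop("`N` must be a positive integer", call. = FALSE)
  }
  N <- as.integer(N)
  # round the quota to kill 1e-16 float noise before flooring
  quota <- round(N * profile$probs, 9)
  base <- floor(quota)
  remainder <- quota - base
  seats <- N - sum(base)
  if (seats > 0) {
    take <- order(-remainder, seq_along(remainder))[seq_len(seats)]
    base[take] <- base[take] + 1
  }
  structure(
    list(counts = stats::setNames(as.integer(base), age_sex_categories()),
         N = N, label = profile$label),
    class = "reference_population"
  )
}

#' @export
print.reference_population <- function(x, ...) {
  cat("Reference population (N =", x$N, "):", x$label, "\n")
  print(x$counts)
  invisible(x)
}

# shared validation for 3-vectors of counts
check_counts3 <- function(counts, what = "counts") {
  if (!is.numeric(counts) || length(counts) != 3L || anyNA(counts) ||
      any(counts < 0) || any(counts != round(counts))) {
    stop(sprintf("`%s` must be 3 non-negative integers over (F, M, JUV)",
                 what), call. = FALSE)
  }
  invisible(TRUE)
}
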