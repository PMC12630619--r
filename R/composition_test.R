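# Assemblage composition test: probability of drawing an observed
# (F, M, JUV) composition from a mortality-structured reference population,
# by Monte Carlo resampling and by exact closed forms.

#' Construct an assemblage composition
#'
#' The observed demographic composition of a skeletal assemblage: counts of
#' adult/adolescent females, adult/adolescent males and juveniles. The MNI
#' (minimum number of individuals) is the sum of the counts.
#'
#' @param counts Non-negative integer vector of length 3 over (F, M, JUV).
#' @param label Assemblage label.
#' @return Object of class `assemblage_composition` with elements `counts`,
#'   `MNI`, `label`.
#' @examples
#' assemblage_composition(c(4, 0, 2), "site A")  # MNI = 6
#' @export
assemblage_composition <- function(counts, label = "assemblage") {
  check_counts3(counts)
  if (sum(counts) < 1) stop("MNI must be positive", call. = FALSE)
  structure(
    list(counts = stats::setNames(as.integer(counts), age_sex_categories()),
         MNI = as.integer(sum(counts)), label = as.character(label)[1L]),
    class = "assemblage_composition"
  )
}

#' @export
print.assemblage_composition <- function(x, ...) {
  cat(sprintf("Assemblage %s: MNI = %d (%s)\n", x$label, x$MNI,
              paste(x$counts, collapse = "/")))
  invisible(x)
}

#' Exact probability of a composition under sampling with replacement
#'
#' The multinomial probability of drawing exactly the observed (F, M, JUV)
#' composition in `MNI` independent draws from a mortality profile:
#' `MNI! / (nF! nM! nJ!) * prod(p_i^n_i)`.
#'
#' @param comp An [assemblage_composition()].
#' @param profile A [mortality_profile()] (or a `reference_population`,
#'   whose proportions `counts/N` are then used).
#' @return Probability in \[0, 1\].
#' @examples
#' comp <- assemblage_composition(c(4, 0, 2))
#' exact_prob_with_replacement(comp, profile_from_counts(c(3, 4, 5)))
#' @export
exact_prob_with_replacement <- function(comp, profile) {
  stopifnot(inherits(comp, "assemblage_composition"))
  if (inherits(profile, "reference_population")) {
    profile <- profile_from_counts(profile$counts, profile$label)
  }
  stopifnot(inherits(profile, "mortality_profile"))
  stats::dmultinom(comp$counts, prob = profile$probs)
}

#' Exact probability of a composition under sampling without replacement
#'
#' The multivariate hypergeometric probability of drawing exactly the
#' observed composition in `MNI` draws without replacement from a finite
#' reference population with category counts `K`:
#' `prod(choose(K_i, n_i)) / choose(N, MNI)`.
#'
#' @param comp An [assemblage_composition()].
#' @param refpop A `reference_population` (see
#'   [build_reference_population()]).
#' @return Probability in \[0, 1\]. Infeasible draws (some `n_i > K_i`)
#'   have probability 0.
#' @examples
#' comp <- assemblage_composition(c(4, 0, 2))
#' pop <- build_reference_population(profile_from_counts(c(3, 4, 5)), 60)
#' exact_prob_without_replacement(comp, pop)  # 409500 / choose(60, 6)
#' @export
exact_prob_without_replacement <- function(comp, refpop) {
  stopifnot(inherits(comp, "assemblage_composition"),
            inherits(refpop, "reference_population"))
  if (comp$MNI > refpop$N) {
    stop("MNI exceeds reference population size", call. = FALSE)
  }
  # lchoose(K, n) is -Inf when n > K, giving probability 0 for infeasible draws
  exp(sum(lchoose(refpop$counts, comp$counts)) -
        lchoose(refpop$N, comp$MNI))
}

#' Significance flags for composition-test probabilities
#'
#' Flags a probability with `"**"` when p < 0.01, `"*"` when
#' 0.01 <= p < 0.05, and `""` otherwise.
#'
#' @param p Numeric vector of probabilities in \[0, 1\].
#' @return Character vector of flags.
#' @export
significance_flags <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("`p` must lie in [0, 1]", call. = FALSE)
  }
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
}

#' Monte Carlo estimate of a composition probability
#'
#' Re-implements the resampling procedure: repeatedly draw `MNI` individuals
#' from the reference population (with or without replacement) and record
#' the fraction of iterations whose (F, M, JUV) counts equal the observed
#' composition exactly. The estimate is unbiased for the matching exact
#' probability ([exact_prob_with_replacement()] /
#' [exact_prob_without_replacement()]).
#'
#' @param comp An [assemblage_composition()].
#' @param refpop A `reference_population`.
#' @param n_iter Number of iterations (default 10000).
#' @param seed Integer seed; the draw is fully reproducible given the seed.
#' @param with_replacement Logical: draw with (`TRUE`) or without (`FALSE`)
#'   replacement.
#' @return Object of class `composition_test_result`: list with `p`, `flag`,
#'   `mode` (`"R"` or `"noR"`), `method` (`"monte_carlo"`), `n_iter`,
#'   `seed`.
#' @export
monte_carlo_prob <- function(comp, refpop, n_iter = 10000, seed = 1,
                             with_replacement = TRUE) {
  stopifnot(inherits(comp, "assemblage_composition"),
            inherits(refpop, "reference_population"))
  if (!is.numeric(n_iter) || n_iter < 1) {
    stop("`n_iter` must be >= 1", call. = FALSE)
  }
  n_iter <- as.integer(n_iter)
  if (!with_replacement && comp$MNI > refpop$N) {
    stop("MNI exceeds reference population size", call. = FALSE)
  }
  target <- comp$counts
  hits <- with_seed(seed, {
    if (with_replacement) {
      draws <- stats::rmultinom(n_iter, comp$MNI, refpop$counts / refpop$N)
      draws[1L, ] == target[1L] & draws[2L, ] == target[2L] &
        draws[3L, ] == target[3L]
    } else {
      pool <- rep.int(seq_len(3L), refpop$counts)
      vapply(seq_len(n_iter), function(i) {
        drawn <- tabulate(pool[sample.int(refpop$N, comp$MNI)], nbins = 3L)
        all(drawn == target)
      }, logical(1L))
    }
  })
  p <- mean(hits)
  structure(
    list(p = p, flag = significance_flags(p),
         mode = if (with_replacement) "R" else "noR",
         method = "monte_carlo", n_iter = n_iter, seed = as.integer(seed)),
    class = "composition_test_result"
  )
}

#' @export
print.composition_test_result <- function(x, ...) {
  cat(sprintf("Composition test (%s, %s): p = %.4g%s  [n_iter = %d, seed = %d]\n",
              x$method, x$mode, x$p, x$flag, x$n_iter, x$seed))
  invisible(x)
}

#' Composition test over a grid of assemblages and demographic models
#'
#' Evaluates every assemblage against every reference model, with and/or
#' without replacement, either analytically (exact pmfs, the default) or by
#' seeded Monte Carlo resampling. Monte Carlo cells use deterministic
#' per-cell substreams derived from `(seed, row, column)` so results do not
#' depend on evaluation order.
#'
#' @param assemblages List of [assemblage_composition()] objects.
#' @param models List of [mortality_profile()] objects, or a list of
#'   `list(profile =, N =)` pairs; plain profiles are scaled to `N`.
#' @param N Reference population size used for profiles without an explicit
#'   `N` (default 60).
#' @param n_iter Monte Carlo iterations per cell (default 10000).
#' @param seed Integer master seed.
#' @param method `"analytic"` (default) or `"monte_carlo"`.
#' @param replacement `"both"` (default), `"R"`, or `"noR"`.
#' @return `data.frame` with columns `assemblage`, `model`, `mode`, `p`,
#'   `flag`, `method`, `n_iter`, `seed` (one row per assemblage x model x
#'   mode).
#' @export
composition_test_table <- function(assemblages, models, N = 60,
                                   n_iter = 10000, seed = 1,
                                   method = c("analytic", "monte_carlo"),
                                   replacement = c("both", "R", "noR")) {
  method <- match.arg(method)
  replacement <- match.arg(replacement)
  if (!length(assemblages) || !length(models)) {
    stop("`assemblages` and `models` must be non-empty lists", call. = FALSE)
  }
  if (inherits(assemblages, "assemblage_composition")) {
    assemblages <- list(assemblages)
  }
  if (inherits(models, "mortality_profile")) models <- list(models)
  modes <- switch(replacement, both = c("R", "noR"), R = "R", noR = "noR")
  rows <- list()
  for (i in seq_along(assemblages)) {
    comp <- assemblages[[i]]
    stopifnot(inherits(comp, "assemblage_composition"))
    for (j in seq_along(models)) {
      m <- models[[j]]
      if (inherits(m, "mortality_profile")) {
        profile <- m
        Nj <- N
      } else {
        profile <- m$profile
        Nj <- if (is.null(m$N)) N else m$N
      }
      refpop <- build_reference_population(profile, Nj)
      for (mode in modes) {
        wr <- mode == "R"
        if (method == "analytic") {
          p <- if (wr) exact_prob_with_replacement(comp, profile)
               else exact_prob_without_replacement(comp, refpop)
          ni <- NA_integer_
        } else {
          cell_seed <- cell_substream(seed, i, j + if (wr) 0L else 1000L)
          res <- monte_carlo_prob(comp, refpop, n_iter = n_iter,
                                  seed = cell_seed, with_replacement = wr)
          p <- res$p
          ni <- n_iter
        }
        rows[[length(rows) + 1L]] <- data.frame(
          assemblage = comp$label, model = profile$label, mode = mode,
          p = p, flag = significance_flags(p), method = method,
          n_iter = ni, seed = as.integer(seed),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# deterministic substream seed for a table cell, kept inside 32-bit range
cell_substream <- function(seed, row, col) {
  as.integer((as.double(seed) * 48271 + row * 16807 + col * 69621) %%
               2147483647)
}

# run code under a temporary RNG state; restores .Random.seed afterwards
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}
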