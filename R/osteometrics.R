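# Osteometric stature reconstruction: maximum length from biomechanical
# length, linear stature regressions with a femur-priority rule, group
# summaries, and Welch's t-test from summary statistics.

#' Reconstruct femoral maximum length from biomechanical length
#'
#' Linear conversion `MaxL = BML * 1.037 + 11.2` (both in mm), used when a
#' femur preserves its biomechanical length but not its maximum length.
#'
#' @param bml_mm Positive femoral biomechanical length(s) in mm.
#' @return Maximum length(s) in mm.
#' @examples
#' maxl_from_bml_femur(373)  # 398.0
#' @export
maxl_from_bml_femur <- function(bml_mm) {
  if (!is.numeric(bml_mm) || anyNA(bml_mm) || any(bml_mm <= 0)) {
    stop("`bml_mm` must be positive", call. = FALSE)
  }
  bml_mm * 1.037 + 11.2
}

#' Create a stature regression specification
#'
#' A linear stature regression `stature_cm = slope * MaxL_cm + intercept`
#' with its standard error of estimate (SEE). Bone lengths are supplied in
#' mm and converted to cm internally.
#'
#' @param id Identifier for the formula.
#' @param element `"femur"`, `"tibia"` or `"radius"`.
#' @param slope,intercept Regression coefficients (input in cm, output cm).
#' @param see Standard error of estimate in cm (>= 0).
#' @return Object of class `regression_spec`.
#' @export
regression_spec <- function(id, element, slope, intercept, see) {
  element <- match.arg(element, c("femur", "tibia", "radius"))
  if (!is.numeric(see) || see < 0) stop("`see` must be >= 0", call. = FALSE)
  structure(list(id = id, element = element, slope = slope,
                 intercept = intercept, see = see,
                 input_unit = "cm", output_unit = "cm"),
            class = "regression_spec")
}

#' Default stature regression registry
#'
#' Sex-pooled linear formulae on femoral and tibial maximum length:
#' femur `2.71 * MaxL_cm + 45.86` (SEE 4.49 cm), tibia
#' `3.29 * MaxL_cm + 47.34` (SEE 4.15 cm). The registry can be replaced or
#' extended with user-supplied [regression_spec()] entries.
#'
#' @return Named list of [regression_spec()] objects.
#' @export
default_stature_registry <- function() {
  list(
    femur = regression_spec("femur_maxl", "femur", 2.71, 45.86, 4.49),
    tibia = regression_spec("tibia_maxl", "tibia", 3.29, 47.34, 4.15)
  )
}

#' Create a long-bone measurement record
#'
#' @param specimen_id Specimen identifier.
#' @param element `"femur"`, `"tibia"` or `"radius"`.
#' @param side `"L"`, `"R"` or `"unknown"`.
#' @param max_length_mm Maximum length in mm, or `NA`.
#' @param biomech_length_mm Biomechanical length in mm, or `NA`.
#' @param individual Optional individual identifier (used by the
#'   femur-priority rule when one individual preserves several bones).
#' @return Object of class `long_bone_measurement`.
#' @export
long_bone_measurement <- function(specimen_id, element,
                                  side = "unknown",
                                  max_length_mm = NA_real_,
                                  biomech_length_mm = NA_real_,
                                  individual = NA_character_) {
  element <- match.arg(element, c("femur", "tibia", "radius"))
  side <- match.arg(side, c("L", "R", "unknown"))
  if (is.na(max_length_mm) && is.na(biomech_length_mm)) {
    stop("at least one of `max_length_mm`, `biomech_length_mm` must be present",
         call. = FALSE)
  }
  for (len in c(max_length_mm, biomech_length_mm)) {
    if (!is.na(len)) {
      if (len <= 0) stop("lengths must be positive", call. = FALSE)
      if (element != "radius" && (len < 150 || len > 650)) {
        warning(sprintf("%s length %.0f mm outside plausibility window [150, 650]",
                        element, len), call. = FALSE)
      }
    }
  }
  structure(list(specimen_id = specimen_id, element = element, side = side,
                 max_length_mm = max_length_mm,
                 biomech_length_mm = biomech_length_mm,
                 individual = individual),
            class = "long_bone_measurement")
}

#' Estimate stature from one long-bone measurement
#'
#' Applies the registry formula for the bone's element to its maximum
#' length. A femur lacking MaxL but preserving BML has MaxL reconstructed
#' via [maxl_from_bml_femur()] first. The estimate carries the formula's
#' SEE; display rounding is left to the caller — aggregation must use the
#' unrounded values.
#'
#' @param m A [long_bone_measurement()].
#' @param registry Named list of [regression_spec()], as from
#'   [default_stature_registry()].
#' @return Object of class `stature_estimate`: list with `specimen_id`,
#'   `stature_cm`, `see_cm`, `formula_id`, `source_element`, `individual`.
#' @examples
#' m <- long_bone_measurement("A", "femur", max_length_mm = 408)
#' estimate_stature(m)$stature_cm  # 156.428
#' @export
estimate_stature <- function(m, registry = default_stature_registry()) {
  stopifnot(inherits(m, "long_bone_measurement"))
  spec <- registry[[m$element]]
  if (is.null(spec)) {
    stop(sprintf("no stature regression registered for element '%s'",
                 m$element), call. = FALSE)
  }
  maxl <- m$max_length_mm
  if (is.na(maxl)) {
    if (m$element == "femur" && !is.na(m$biomech_length_mm)) {
      maxl <- maxl_from_bml_femur(m$biomech_length_mm)
    } else {
      stop(sprintf("specimen %s: maximum length absent and not reconstructible",
                   m$specimen_id), call. = FALSE)
    }
  }
  stature <- spec$slope * (maxl / 10) + spec$intercept
  structure(list(specimen_id = m$specimen_id, stature_cm = stature,
                 see_cm = spec$see, formula_id = spec$id,
                 source_element = m$element, individual = m$individual),
            class = "stature_estimate")
}

#' @export
print.stature_estimate <- function(x, ...) {
  cat(sprintf("%s: %.0f cm ± %.2f (%s)\n", x$specimen_id, x$stature_cm,
              x$see_cm, x$source_element))
  invisible(x)
}

#' Estimate statures for a table of measurements with femur priority
#'
#' Vectorized stature estimation over a measurement table. When
#' `prefer_femur = TRUE` and one individual preserves both a femur and a
#' tibia, only the femoral estimate is kept for that individual (distal limb
#' segments are relatively short in Neandertals, so tibial formulae are less
#' reliable across groups).
#'
#' @param measurements `data.frame` with columns `specimen_id`, `element`,
#'   and `maxl_mm` and/or `bml_mm` (NA allowed); optional columns `side`,
#'   `individual`, `group`.
#' @param registry Stature regression registry.
#' @param prefer_femur Apply the femur-priority rule per individual
#'   (default `TRUE`; requires an `individual` column to group bones).
#' @return `data.frame` with columns `specimen_id`, `individual`, `group`,
#'   `source_element`, `stature_cm`, `see_cm`, `formula_id`.
#' @export
estimate_statures <- function(measurements,
                              registry = default_stature_registry(),
                              prefer_femur = TRUE) {
  req <- c("specimen_id", "element")
  if (!all(req %in% names(measurements))) {
    stop("`measurements` needs columns specimen_id, element", call. = FALSE)
  }
  n <- nrow(measurements)
  get_col <- function(nm, default) {
    if (nm %in% names(measurements)) measurements[[nm]] else rep(default, n)
  }
  maxl <- get_col("maxl_mm", NA_real_)
  bml <- get_col("bml_mm", NA_real_)
  side <- get_col("side", "unknown")
  indiv <- get_col("individual", NA_character_)
  group <- get_col("group", NA_character_)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    m <- long_bone_measurement(measurements$specimen_id[i],
                               measurements$element[i], side[i],
                               maxl[i], bml[i], indiv[i])
    est <- estimate_stature(m, registry)
    out[[i]] <- data.frame(specimen_id = est$specimen_id,
                           individual = indiv[i], group = group[i],
                           source_element = est$source_element,
                           stature_cm = est$stature_cm, see_cm = est$see_cm,
                           formula_id = est$formula_id,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (prefer_femur && any(!is.na(res$individual))) {
    keep <- rep(TRUE, nrow(res))
    for (id in unique(res$individual[!is.na(res$individual)])) {
      sel <- which(res$individual == id)
      if (any(res$source_element[sel] == "femur") &&
          any(res$source_element[sel] != "femur")) {
        keep[sel[res$source_element[sel] != "femur"]] <- FALSE
      }
    }
    res <- res[keep, , drop = FALSE]
    rownames(res) <- NULL
  }
  res
}

#' Summarize a group of stature estimates
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of the
#' unrounded statures.
#'
#' @param statures Numeric vector of statures in cm, or a `data.frame` from
#'   [estimate_statures()] (its `stature_cm` column is used).
#' @return List with `mean_cm`, `sd_cm` (`NA` when n < 2) and `n`.
#' @export
group_stature_summary <- function(statures) {
  if (is.data.frame(statures)) statures <- statures$stature_cm
  statures <- statures[!is.na(statures)]
  n <- length(statures)
  if (n < 1) stop("no statures to summarize", call. = FALSE)
  list(mean_cm = mean(statures),
       sd_cm = if (n >= 2) stats::sd(statures) else NA_real_,
       n = n)
}

#' Welch's t-test from summary statistics
#'
#' Two-sided Welch (unequal-variances) t-test computed from group means,
#' standard deviations and sizes:
#' `t = (mean2 - mean1) / sqrt(sd1^2/n1 + sd2^2/n2)`, with
#' Welch--Satterthwaite degrees of freedom. Useful when only published
#' summaries of a comparative sample are available.
#'
#' @param mean1,sd1,n1 First group summary (n1 >= 2, sd1 >= 0).
#' @param mean2,sd2,n2 Second group summary.
#' @return List with `t`, `df`, `p_two_sided`.
#' @examples
#' welch_t_test(151.56, 5.05, 5, 162.89, 8.20, 17)
#' @export
welch_t_test <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0",
                               call. = FALSE)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  se2 <- v1 + v2
  if (se2 == 0) {
    # degenerate variances: identical means give t = 0, p = 1
    if (mean1 == mean2) return(list(t = 0, df = Inf, p_two_sided = 1))
    return(list(t = sign(mean2 - mean1) * Inf, df = Inf, p_two_sided = 0))
  }
  t <- (mean2 - mean1) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p_two_sided = 2 * stats::pt(-abs(t), df))
}
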