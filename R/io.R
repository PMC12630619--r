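# Readers and writers for the package's plain-text formats: contour CSV,
# TPS landmark files, profile/population CSV, and the tabular outputs.
# Every writer emits a '#' header comment recording tool version and
# parameters; every reader tolerates and ignores such headers.

op_header <- function(...) {
  extra <- paste(c(...), collapse = "; ")
  sprintf("# osteoprofile %s%s",
          as.character(utils::packageVersion("osteoprofile")),
          if (nzchar(extra)) paste0("; ", extra) else "")
}

write_csv_with_header <- function(df, path, ...) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(op_header(...), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_csv_skip_comments <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write section contours to CSV
#'
#' Long format, one vertex per row, with columns `specimen_id`, `element`,
#' `side`, `location_label`, `ring` (`peri`/`endo`), `vertex_index`, `x_mm`,
#' `y_mm`.
#'
#' @param sections List of [section_contour()] objects (or a single one).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_contours <- function(sections, path) {
  if (inherits(sections, "section_contour")) sections <- list(sections)
  rows <- lapply(sections, function(s) {
    rbind(
      data.frame(specimen_id = s$specimen_id, element = s$element,
                 side = s$side, location_label = s$location_label,
                 ring = "peri", vertex_index = seq_len(nrow(s$periosteal)),
                 x_mm = s$periosteal[, 1L], y_mm = s$periosteal[, 2L]),
      data.frame(specimen_id = s$specimen_id, element = s$element,
                 side = s$side, location_label = s$location_label,
                 ring = "endo", vertex_index = seq_len(nrow(s$endosteal)),
                 x_mm = s$endosteal[, 1L], y_mm = s$endosteal[, 2L]))
  })
  write_csv_with_header(do.call(rbind, rows), path, "contour CSV")
}

#' Read section contours from CSV
#'
#' Reads the format written by [write_contours()], validates every section
#' (paired rings, simplicity, endosteal inside periosteal) and preserves the
#' file's section order.
#'
#' @param path Input file.
#' @return List of [section_contour()] objects.
#' @export
read_contours <- function(path) {
  df <- read_csv_skip_comments(path)
  need <- c("specimen_id", "element", "side", "location_label", "ring",
            "vertex_index", "x_mm", "y_mm")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("contour CSV is missing columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  key <- paste(df$specimen_id, df$location_label, sep = "\r")
  out <- list()
  for (k in unique(key)) {
    sub <- df[key == k, , drop = FALSE]
    peri <- sub[sub$ring == "peri", , drop = FALSE]
    endo <- sub[sub$ring == "endo", , drop = FALSE]
    if (!nrow(peri) || !nrow(endo)) {
      stop(sprintf("section %s: unpaired ring (needs both peri and endo)",
                   sub$specimen_id[1L]), call. = FALSE)
    }
    peri <- peri[order(peri$vertex_index), , drop = FALSE]
    endo <- endo[order(endo$vertex_index), , drop = FALSE]
    out[[length(out) + 1L]] <- section_contour(
      sub$specimen_id[1L], sub$element[1L],
      cbind(peri$x_mm, peri$y_mm), cbind(endo$x_mm, endo$y_mm),
      side = sub$side[1L], location_label = as.character(sub$location_label[1L]))
  }
  out
}

#' Write landmark configurations to a TPS file
#'
#' Standard TPS interchange format: an `LM=` line, one `x y` coordinate
#' line per landmark, then `ID=` (and `SCALE=` if a scale is supplied).
#'
#' @param configs List of [landmark_configuration()] objects.
#' @param path Output file.
#' @param scale Optional numeric scale written as `SCALE=` (recycled).
#' @return `path`, invisibly.
#' @export
write_tps <- function(configs, path, scale = NULL) {
  if (inherits(configs, "landmark_configuration")) configs <- list(configs)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    writeLines(sprintf("LM=%d", nrow(cfg$points)), con)
    writeLines(sprintf("%.9g %.9g", cfg$points[, 1L], cfg$points[, 2L]), con)
    writeLines(sprintf("ID=%s", cfg$specimen_id), con)
    if (!is.null(scale)) {
      writeLines(sprintf("SCALE=%.9g", rep_len(scale, length(configs))[i]),
                 con)
    }
  }
  invisible(path)
}

#' Read landmark configurations from a TPS file
#'
#' Parses `LM=` blocks; coordinates are multiplied by the record's `SCALE=`
#' when present (the TPS convention). All records must have the same
#' landmark count.
#'
#' @param path Input file.
#' @return List of [landmark_configuration()] objects.
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  lm_at <- grep("^LM=", lines)
  if (!length(lm_at)) stop("no LM= records found", call. = FALSE)
  ends <- c(lm_at[-1L] - 1L, length(lines))
  out <- vector("list", length(lm_at))
  for (i in seq_along(lm_at)) {
    block <- lines[lm_at[i]:ends[i]]
    n_lm <- as.integer(sub("^LM=", "", block[1L]))
    coord_lines <- block[seq.int(2L, 1L + n_lm)]
    coords <- do.call(rbind, lapply(strsplit(coord_lines, "[ \t]+"),
                                    as.numeric))
    if (nrow(coords) != n_lm || anyNA(coords)) {
      stop(sprintf("TPS record %d: expected %d coordinate lines", i, n_lm),
           call. = FALSE)
    }
    rest <- block[-seq_len(1L + n_lm)]
    id <- sub("^ID=", "", grep("^ID=", rest, value = TRUE)[1L])
    if (is.na(id)) id <- sprintf("record_%d", i)
    sc <- grep("^SCALE=", rest, value = TRUE)
    if (length(sc)) coords <- coords * as.numeric(sub("^SCALE=", "", sc[1L]))
    out[[i]] <- landmark_configuration(coords, specimen_id = id)
  }
  counts <- vapply(out, function(c0) nrow(c0$points), integer(1L))
  if (length(unique(counts)) != 1L) {
    stop("inconsistent LM= counts across TPS records", call. = FALSE)
  }
  out
}

#' Write mortality profiles / reference populations to CSV
#'
#' Flat format with columns `label`, `F`, `M`, `JUV`, `N`. Profiles are
#' stored as their probabilities with `N = NA`; reference populations as
#' integer counts with their `N`.
#'
#' @param x List of [mortality_profile()] and/or `reference_population`
#'   objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(x, path) {
  if (inherits(x, c("mortality_profile", "reference_population"))) {
    x <- list(x)
  }
  rows <- lapply(x, function(p) {
    if (inherits(p, "mortality_profile")) {
      data.frame(label = p$label, F = p$probs[[1L]], M = p$probs[[2L]],
                 JUV = p$probs[[3L]], N = NA_integer_)
    } else {
      data.frame(label = p$label, F = p$counts[[1L]], M = p$counts[[2L]],
                 JUV = p$counts[[3L]], N = p$N)
    }
  })
  write_csv_with_header(do.call(rbind, rows), path, "profiles CSV")
}

#' Read mortality profiles / reference populations from CSV
#'
#' Rows with `N` present are returned as `reference_population` objects (the
#' F/M/JUV columns read as counts); rows with `N` empty as
#' [mortality_profile()] objects (columns read as probabilities, or counts
#' that are normalized if they do not sum to 1).
#'
#' @param path Input file.
#' @return List of profile/population objects.
#' @export
read_profiles <- function(path) {
  df <- read_csv_skip_comments(path)
  need <- c("label", "F", "M", "JUV")
  if (!all(need %in% names(df))) {
    stop("profiles CSV needs columns label, F, M, JUV (and optionally N)",
         call. = FALSE)
  }
  if (!"N" %in% names(df)) df$N <- NA_integer_
  lapply(seq_len(nrow(df)), function(i) {
    v <- c(df$F[i], df$M[i], df$JUV[i])
    if (!is.na(df$N[i])) {
      pop <- build_reference_population(profile_from_counts(v, df$label[i]),
                                        df$N[i])
      if (sum(v) == df$N[i]) pop$counts[] <- as.integer(v)
      pop
    } else if (abs(sum(v) - 1) <= 1e-9) {
      mortality_profile(v / sum(v), df$label[i])
    } else {
      profile_from_counts(v, df$label[i])
    }
  })
}

#' Write a composition-test result grid to CSV
#'
#' @param table `data.frame` from [composition_test_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_composition_table <- function(table, path) {
  write_csv_with_header(table, path,
                        sprintf("composition test; seed=%s; n_iter=%s",
                                table$seed[1L], table$n_iter[1L]))
}

#' Write a CSG property table to CSV
#'
#' One row per section with the standard columns (CA, TA, Ix, Iy, Imax,
#' Imin, Zp and companions), as produced by [csg_table()].
#'
#' @param table `data.frame` from [csg_table()], or a list of sections.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_csg_table <- function(table, path) {
  if (!is.data.frame(table)) table <- csg_table(table)
  write_csv_with_header(table, path, "CSG properties")
}
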