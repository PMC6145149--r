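# Delimited-text and JSON interchange. TSV is the default dialect; CSV is
# available everywhere. '#'-prefixed lines carry metadata (notably
# '#thickness_um='). Units are fixed in column names (um, um2, nm, fl) to
# prevent silent unit drift; fl = um^3.

delim_for <- function(path, format = NULL) {
  if (!is.null(format)) {
    format <- match.arg(format, c("tsv", "csv"))
    return(if (format == "csv") "," else "\t")
  }
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(x == round(x) & abs(x) < 1e15,
                sprintf("%.0f", x), sprintf("%.17g", x)))
}

write_delim_file <- function(df, path, sep, meta = character()) {
  cols <- lapply(df, function(col) {
    if (is.numeric(col)) fmt_num(col) else as.character(col)
  })
  lines <- c(
    meta,
    paste(names(df), collapse = sep),
    do.call(paste, c(cols, sep = sep))
  )
  writeLines(lines, path)
  invisible(path)
}

read_meta <- function(path) {
  lines <- readLines(path, n = 50L)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- regmatches(meta_lines,
                   regexec("^#\\s*([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", meta_lines))
  out <- list()
  for (m in kv) {
    if (length(m) == 3) out[[m[2]]] <- m[3]
  }
  out
}

#' Read serial-section stacks from a delimited file
#'
#' Expects a header row with the interchange columns (`cell_id`,
#' `section_index`, `p_om_um`, `p_pm_um`, `a_om_um2`, `a_pm_um2`,
#' `minor_om_um`, `major_om_um`, `minor_pm_um`, `major_pm_um`, `ribosomes`,
#' `om_thickness_nm`, `pm_thickness_nm`) and the section thickness either
#' in a `#thickness_um=` metadata line or via the `thickness` argument.
#' Rows are grouped by `cell_id` and ordered by `section_index`; duplicate
#' (cell, index) pairs are a hard error.
#'
#' @param path input file (TSV by default, CSV by extension or `format`).
#' @param thickness section thickness in um, overriding the file metadata.
#' @param format `"tsv"` or `"csv"`; inferred from the extension if `NULL`.
#' @return a list of `section_stack` objects, in order of first appearance.
#' @export
read_section_stacks <- function(path, thickness = NULL, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  meta <- read_meta(path)
  if (is.null(thickness)) {
    if (is.null(meta$thickness_um)) {
      stop("section thickness not found: provide '#thickness_um=' metadata ",
           "or the 'thickness' argument", call. = FALSE)
    }
    thickness <- as.numeric(meta$thickness_um)
  }
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path, format),
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("cell_id", section_columns)
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  ids <- unique(df$cell_id)
  lapply(ids, function(id) {
    new_section_stack(id, thickness,
                      df[df$cell_id == id, section_columns, drop = FALSE])
  })
}

#' Write serial-section stacks to a delimited file
#'
#' Inverse of [read_section_stacks()]. All stacks must share one section
#' thickness, recorded in a `#thickness_um=` metadata line. Numeric values
#' are written with 17 significant digits, so a write/read round trip is
#' lossless.
#'
#' @param stacks a `section_stack` or list of them.
#' @param path output file.
#' @inheritParams read_section_stacks
#' @return the path, invisibly.
#' @export
write_section_stacks <- function(stacks, path, format = NULL) {
  if (inherits(stacks, "section_stack")) stacks <- list(stacks)
  th <- unique(vapply(stacks, function(s) s$thickness, numeric(1)))
  if (length(th) != 1) {
    stop("all stacks in one file must share a section thickness",
         call. = FALSE)
  }
  df <- do.call(rbind, lapply(stacks, function(s) {
    cbind(cell_id = s$cell_id, s$sections)
  }))
  write_delim_file(df, path, delim_for(path, format),
                   meta = sprintf("#thickness_um=%s", fmt_num(th)))
}

#' Write a profile table with summary footer rows
#'
#' Emits one row per cell plus `Average`, `SD`, `Min` and `Max` footer rows
#' (computed at full precision, then rounded), mirroring the layout of
#' published structome tables. With a single profile the SD row is
#' suppressed and a metadata note written instead. The JSON format carries
#' full-precision per-cell values and no footer, and parses back to
#' identical values.
#'
#' @param profiles a profile table ([cell_profile] rows).
#' @param path output file.
#' @param format `"tsv"`, `"csv"` or `"json"`; inferred from the extension
#'   if `NULL`.
#' @param rounding apply the report rounding policy
#'   ([round_profile_table()]) to delimited output? Default `TRUE`.
#' @return the path, invisibly.
#' @export
write_profile_table <- function(profiles, path, format = NULL,
                                rounding = TRUE) {
  stopifnot(nrow(profiles) >= 1)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("csv", "json")) ext else "tsv"
  }
  format <- match.arg(format, c("tsv", "csv", "json"))
  if (format == "json") {
    jsonlite::write_json(as.data.frame(profiles), path, auto_unbox = FALSE,
                         digits = NA, na = "null")
    return(invisible(path))
  }
  num_cols <- setdiff(names(profiles)[vapply(profiles, is.numeric, TRUE)],
                      "n_sections")
  footer_of <- function(stat_name, fun) {
    row <- profiles[1, , drop = FALSE]
    row$cell_id <- stat_name
    row$n_sections <- NA_integer_
    for (m in num_cols) row[[m]] <- fun(profiles[[m]])
    row
  }
  body <- profiles
  meta <- character()
  footers <- list(footer_of("Average", mean))
  if (nrow(profiles) > 1) {
    footers <- c(footers, list(footer_of("SD", stats::sd)))
  } else {
    meta <- "#note=single profile: SD row suppressed"
  }
  footers <- c(footers, list(footer_of("Min", min), footer_of("Max", max)))
  out <- rbind(body, do.call(rbind, footers))
  if (rounding) out <- round_profile_table(out)
  write_delim_file(as.data.frame(out), path, delim_for(path, format),
                   meta = meta)
}

#' Read a profile table
#'
#' Reads delimited or JSON profile tables written by
#' [write_profile_table()]; footer rows (`Average`, `SD`, `Min`, `Max`) are
#' dropped from delimited input.
#'
#' @inheritParams read_section_stacks
#' @return a profile table.
#' @export
read_profile_table <- function(path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("csv", "json")) ext else "tsv"
  }
  format <- match.arg(format, c("tsv", "csv", "json"))
  df <- if (format == "json") {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.table(path, header = TRUE, sep = delim_for(path, format),
                      comment.char = "#", stringsAsFactors = FALSE)
  }
  df <- df[!df$cell_id %in% c("Average", "SD", "Min", "Max"), , drop = FALSE]
  missing <- setdiff(profile_columns, names(df))
  if (length(missing)) {
    stop("missing profile columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("cell_profile", "data.frame")
  df
}

#' Write a metric-summary or comparison table
#'
#' @param x a data frame (e.g. from [summarize_profiles()] or
#'   [compare_profiles()]).
#' @param path output file; `.json` writes full-precision JSON.
#' @param format `"tsv"`, `"csv"` or `"json"`; inferred if `NULL`.
#' @return the path, invisibly.
#' @export
write_table <- function(x, path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("csv", "json")) ext else "tsv"
  }
  format <- match.arg(format, c("tsv", "csv", "json"))
  if (format == "json") {
    jsonlite::write_json(as.data.frame(x), path, auto_unbox = FALSE,
                         digits = NA, na = "null")
    return(invisible(path))
  }
  write_delim_file(as.data.frame(x), path, delim_for(path, format))
}

#' Save / load a doubling-time calibration model as JSON
#'
#' @param model a [doubling_model()].
#' @param path JSON file path.
#' @return `write_doubling_model()` returns the path invisibly;
#'   `read_doubling_model()` the model.
#' @export
write_doubling_model <- function(model, path) {
  stopifnot(inherits(model, "doubling_model"))
  jsonlite::write_json(list(a = model$a, b = model$b,
                            provenance = model$provenance),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_doubling_model
#' @export
read_doubling_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  doubling_model(x$a, x$b, provenance = x$provenance %||% "loaded from JSON")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a simulation configuration (YAML or JSON)
#'
#' The configuration lists the synthetic cells to generate and the slicing
#' parameters:
#' ```yaml
#' thickness_um: 0.04
#' noise_cv: 0
#' seed: 1
#' cells:
#'   - cell_id: sim-1
#'     radius_om: 0.29
#'     length_om: 3.54
#'     ribosome_density: 1170
#' ```
#' Unspecified per-cell fields take the [spherocylinder_model()] defaults.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON config file.
#' @return a list with `models` (list of [spherocylinder_model()]),
#'   `thickness`, `noise_cv` and `seed`.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$cells) || !length(cfg$cells)) {
    stop("config must list at least one cell under 'cells'", call. = FALSE)
  }
  models <- lapply(seq_along(cfg$cells), function(i) {
    spec <- cfg$cells[[i]]
    allowed <- names(formals(spherocylinder_model))
    unknown <- setdiff(names(spec), allowed)
    if (length(unknown)) {
      stop("unknown cell field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    if (is.null(spec$cell_id)) spec$cell_id <- sprintf("sim-%d", i)
    do.call(spherocylinder_model, spec)
  })
  list(models = models,
       thickness = as.numeric(cfg$thickness_um %||% 0.04),
       noise_cv = as.numeric(cfg$noise_cv %||% 0),
       seed = as.integer(cfg$seed %||% 1L))
}

#' Bundled reference dataset: seven M. smegmatis cells
#'
#' Published structome measurements of seven exponential-phase
#' *Mycolicibacterium smegmatis* cells, each reconstructed from complete
#' serial ultrathin sections (40-nm nominal thickness) spanning the cell
#' pole to pole: per-cell length, OM/PM diameters, aspect ratio, surface
#' areas, compartment volumes, and ribosome totals and densities. Lengths
#' are the published, externally measured values (they are not section
#' count times nominal thickness; see the package vignette).
#'
#' @return a profile table with 7 [cell_profile] rows.
#' @export
#' @examples
#' summarize_profiles(msmegmatis_profiles(), "M. smegmatis")
msmegmatis_profiles <- function() {
  path <- system.file("extdata", "msmegmatis_structome.tsv",
                      package = "structome", mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  df$cell_id <- as.character(df$cell_id)
  class(df) <- c("cell_profile", "data.frame")
  df
}

#' Bundled species-level structome summaries
#'
#' Published summary statistics (n, mean, SD) of structome metrics for the
#' species analysed by the same serial-section methodology: Myojin spiral
#' and amorphous bacteria, *M. tuberculosis*, *M. smegmatis*, *E. coli*,
#' *E. dermatitidis* and *S. cerevisiae*. Used for cross-species
#' comparisons via [t_test_from_summaries()] / [compare_profiles()].
#'
#' @return a data frame with columns `group`, `metric`, `n`, `mean`, `sd`.
#' @export
species_summaries <- function() {
  path <- system.file("extdata", "species_summaries.tsv",
                      package = "structome", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
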