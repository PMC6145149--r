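# Core containers: the per-section measurement stack (raw input) and the
# per-cell structome profile (the pipeline's output row).

section_columns <- c(
  "section_index", "p_om_um", "p_pm_um", "a_om_um2", "a_pm_um2",
  "minor_om_um", "major_om_um", "minor_pm_um", "major_pm_um",
  "ribosomes", "om_thickness_nm", "pm_thickness_nm"
)

profile_columns <- c(
  "cell_id", "n_sections", "length", "diam_om", "diam_pm", "aspect_ratio",
  "surf_om", "surf_pm", "vol_whole", "vol_om", "vol_periplasm", "vol_pm",
  "vol_cytoplasm", "ribosomes_total", "ribosome_density"
)

#' Construct a serial-section measurement stack
#'
#' A `section_stack` holds the ordered per-section morphometry of one cell:
#' OM/PM perimeters (um), cross-sectional areas (um^2), minor/major axes
#' (um), the per-section ribosome count, and optional membrane thicknesses
#' (nm), together with the section thickness.
#'
#' @param cell_id cell label.
#' @param thickness section thickness, um; must be positive.
#' @param sections data frame with (at least) the interchange columns:
#'   `section_index`, `p_om_um`, `p_pm_um`, `a_om_um2`, `a_pm_um2`,
#'   `minor_om_um`, `major_om_um`, `minor_pm_um`, `major_pm_um`,
#'   `ribosomes`, `om_thickness_nm`, `pm_thickness_nm`.
#' @param offset axial offset used when the stack was cut synthetically
#'   (internal bookkeeping; optional).
#' @param length_um an externally supplied cell length (um), if one
#'   accompanies the stack (see [cell_length()]).
#' @return an object of class `"section_stack"`.
#' @export
new_section_stack <- function(cell_id, thickness, sections, offset = NULL,
                              length_um = NULL) {
  stopifnot_scalar_number(thickness, "thickness", 0, strict = TRUE)
  if (!is.data.frame(sections) || nrow(sections) < 1L) {
    stop("'sections' must be a data frame with at least one row", call. = FALSE)
  }
  missing <- setdiff(section_columns, names(sections))
  if (length(missing)) {
    stop("sections are missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sections <- sections[order(sections$section_index), section_columns,
                       drop = FALSE]
  rownames(sections) <- NULL
  idx <- sections$section_index
  if (anyDuplicated(idx)) {
    dup <- idx[duplicated(idx)][1]
    stop(sprintf("duplicate section index %d in cell '%s'", dup, cell_id),
         call. = FALSE)
  }
  num <- c("p_om_um", "p_pm_um", "a_om_um2", "a_pm_um2",
           "minor_om_um", "major_om_um", "minor_pm_um", "major_pm_um")
  for (col in num) {
    if (any(is.finite(sections[[col]]) & sections[[col]] < 0)) {
      stop(sprintf("negative values in column '%s' of cell '%s'", col, cell_id),
           call. = FALSE)
    }
  }
  if (any(!is.na(sections$ribosomes) & sections$ribosomes < 0)) {
    stop(sprintf("negative ribosome count in cell '%s'", cell_id),
         call. = FALSE)
  }
  structure(
    list(cell_id = as.character(cell_id), thickness = thickness,
         sections = sections, offset = offset, length_um = length_um),
    class = "section_stack"
  )
}

#' @export
print.section_stack <- function(x, ...) {
  cat(sprintf("Serial section stack: cell '%s', %d sections x %.3f um\n",
              x$cell_id, nrow(x$sections), x$thickness))
  cat(sprintf("  total ribosomes counted: %s\n",
              format(sum(x$sections$ribosomes), big.mark = ",")))
  invisible(x)
}

#' Construct a per-cell structome profile row
#'
#' The profile is the quantitative description of one cell: 1D (length,
#' OM/PM diameters, aspect ratio), 2D (OM/PM surface areas, um^2), 3D
#' (whole-cell, OM shell, periplasm, PM shell, cytoplasm volumes, fl) and
#' ribosome enumeration (total count and density per 0.1 fl cytoplasm).
#' Profiles are one-row data frames; multiple cells combine with `rbind()`
#' into a profile table.
#'
#' @param cell_id,n_sections,length,diam_om,diam_pm,aspect_ratio profile
#'   fields (um for lengths/diameters).
#' @param surf_om,surf_pm surface areas, um^2.
#' @param vol_whole,vol_om,vol_periplasm,vol_pm,vol_cytoplasm volumes, fl.
#' @param ribosomes_total,ribosome_density ribosome count and density per
#'   0.1 fl cytoplasm.
#' @return a data frame of classes `c("cell_profile", "data.frame")`.
#' @name cell_profile
#' @export
new_cell_profile <- function(cell_id, n_sections, length, diam_om, diam_pm,
                             aspect_ratio, surf_om, surf_pm, vol_whole,
                             vol_om, vol_periplasm, vol_pm, vol_cytoplasm,
                             ribosomes_total, ribosome_density) {
  out <- data.frame(
    cell_id = as.character(cell_id), n_sections = n_sections,
    length = length, diam_om = diam_om, diam_pm = diam_pm,
    aspect_ratio = aspect_ratio, surf_om = surf_om, surf_pm = surf_pm,
    vol_whole = vol_whole, vol_om = vol_om, vol_periplasm = vol_periplasm,
    vol_pm = vol_pm, vol_cytoplasm = vol_cytoplasm,
    ribosomes_total = ribosomes_total, ribosome_density = ribosome_density,
    stringsAsFactors = FALSE
  )
  class(out) <- c("cell_profile", "data.frame")
  out
}

#' Apply report-table rounding to a profile table
#'
#' Lengths, diameters, areas, volumes and aspect ratios are rounded
#' half-away-from-zero to 2 decimal places; ribosome totals and densities
#' to the nearest 10. Internal computations are always carried at full
#' precision; this is applied at report time only.
#'
#' @param profiles a profile table ([cell_profile] rows).
#' @return the rounded table.
#' @export
round_profile_table <- function(profiles) {
  two_dp <- c("length", "diam_om", "diam_pm", "aspect_ratio", "surf_om",
              "surf_pm", "vol_whole", "vol_om", "vol_periplasm", "vol_pm",
              "vol_cytoplasm")
  for (col in intersect(two_dp, names(profiles))) {
    profiles[[col]] <- round_half_up(profiles[[col]], 2)
  }
  for (col in intersect(c("ribosomes_total", "ribosome_density"),
                        names(profiles))) {
    profiles[[col]] <- round_to_10(profiles[[col]])
  }
  profiles
}

#' @export
print.cell_profile <- function(x, digits = NULL, ...) {
  cat(sprintf("Structome profile (%d cell%s):\n", nrow(x),
              if (nrow(x) == 1) "" else "s"))
  print.data.frame(round_profile_table(x), row.names = FALSE)
  invisible(x)
}
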