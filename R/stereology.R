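# Stereology estimators: per-cell structome metrics from a serial-section
# measurement stack. Conventions follow quantitative structome analysis of
# rod-shaped bacteria on ~40-nm serial ultrathin TEM sections: lengths from
# section counts, surface areas by the trapezoid rule over per-section
# perimeters, volumes as Cavalieri sums of cross-sectional areas, the
# periplasm by subtraction, and ribosome density per 0.1 fl of cytoplasm.

#' Cell length from a section stack
#'
#' In `section_count` mode the length is the number of sections times the
#' section thickness. In `supplied` mode an externally measured length
#' carried with the stack (or given via `length_um`) is passed through —
#' needed when published per-cell lengths are not consistent with section
#' count times nominal thickness.
#'
#' @param stack a `section_stack`.
#' @param mode `"section_count"` (default) or `"supplied"`.
#' @param length_um length to use in `supplied` mode, um; defaults to the
#'   stack's own `length_um` field.
#' @return length in um.
#' @export
cell_length <- function(stack, mode = c("section_count", "supplied"),
                        length_um = stack$length_um) {
  stopifnot(inherits(stack, "section_stack"))
  mode <- match.arg(mode)
  if (mode == "section_count") {
    return(nrow(stack$sections) * stack$thickness)
  }
  if (is.null(length_um) || !is.finite(length_um)) {
    stop("supplied mode requires a length accompanying the stack",
         call. = FALSE)
  }
  length_um
}

#' Cell diameter from per-section minor axes
#'
#' @param stack a `section_stack`.
#' @param boundary `"om"` (whole cell) or `"pm"` (cytoplasm).
#' @param estimator `"median_central"` (default): median of the minor-axis
#'   values over the central 50\% of sections, excluding the tapering poles;
#'   `"mean_all"`: mean over all sections with a positive axis; `"max"`:
#'   largest observed minor axis.
#' @return diameter in um.
#' @export
cell_diameter <- function(stack, boundary = c("om", "pm"),
                          estimator = c("median_central", "mean_all", "max")) {
  stopifnot(inherits(stack, "section_stack"))
  boundary <- match.arg(boundary)
  estimator <- match.arg(estimator)
  minor <- stack$sections[[paste0("minor_", boundary, "_um")]]
  if (all(!is.finite(minor) | minor <= 0)) {
    stop(sprintf("no positive %s minor-axis values", toupper(boundary)),
         call. = FALSE)
  }
  switch(estimator,
    median_central = {
      n <- length(minor)
      lo <- floor(n / 4) + 1L
      hi <- n - floor(n / 4)
      stats::median(minor[lo:hi])
    },
    mean_all = mean(minor[is.finite(minor) & minor > 0]),
    max = max(minor, na.rm = TRUE)
  )
}

#' Aspect ratio
#'
#' Cell length divided by OM diameter.
#'
#' @param length cell length, um.
#' @param diam_om OM diameter, um; must be positive.
#' @return unitless ratio.
#' @export
aspect_ratio <- function(length, diam_om) {
  if (any(diam_om <= 0)) stop("'diam_om' must be positive", call. = FALSE)
  length / diam_om
}

#' Membrane surface area by the trapezoid rule
#'
#' Reconstructs the OM or PM surface as a stack of trapezoids: for each
#' pair of consecutive sections the boundary's perimeters are the two
#' parallel sides and the section thickness the height, so
#' `S = sum_{i=2..n} (p_i + p_{i-1}) / 2 * t`. No end-cap correction is
#' applied beyond the first/last half-interval; the resulting
#' pole-cap underestimate is documented in the package vignette.
#'
#' @inheritParams cell_diameter
#' @return surface area, um^2.
#' @export
surface_area <- function(stack, boundary = c("om", "pm")) {
  stopifnot(inherits(stack, "section_stack"))
  boundary <- match.arg(boundary)
  p <- stack$sections[[paste0("p_", boundary, "_um")]]
  if (length(p) < 2) {
    stop("surface area needs at least 2 sections", call. = FALSE)
  }
  if (any(p < 0)) stop("negative perimeter", call. = FALSE)
  sum((p[-1] + p[-length(p)]) / 2) * stack$thickness
}

#' Compartment volume by the Cavalieri method
#'
#' Each section contributes a prism with the traced cross-sectional area as
#' base and the section thickness as height: `V = sum_i a_i * t`. With the
#' OM-lined areas this is the whole-cell volume; with the PM-lined areas,
#' the cytoplasmic volume. 1 fl = 1 um^3.
#'
#' @inheritParams cell_diameter
#' @return volume, fl.
#' @export
compartment_volume <- function(stack, boundary = c("om", "pm")) {
  stopifnot(inherits(stack, "section_stack"))
  boundary <- match.arg(boundary)
  a <- stack$sections[[paste0("a_", boundary, "_um2")]]
  if (any(a < 0)) stop("negative cross-sectional area", call. = FALSE)
  sum(a) * stack$thickness
}

#' Membrane shell volume from perimeter and membrane thickness
#'
#' Thin-shell approximation: each section contributes perimeter x membrane
#' thickness x section thickness, so `V = sum_i p_i * tau_i * t` with
#' `tau_i` the membrane thickness (converted from nm to um).
#'
#' @inheritParams cell_diameter
#' @param membrane `"om"` or `"pm"`.
#' @param thickness_nm optional constant membrane thickness (nm) overriding
#'   the per-section column.
#' @return shell volume, fl.
#' @export
shell_volume <- function(stack, membrane = c("om", "pm"), thickness_nm = NULL) {
  stopifnot(inherits(stack, "section_stack"))
  membrane <- match.arg(membrane)
  p <- stack$sections[[paste0("p_", membrane, "_um")]]
  tau_nm <- if (!is.null(thickness_nm)) {
    rep(thickness_nm, length(p))
  } else {
    stack$sections[[paste0(membrane, "_thickness_nm")]]
  }
  if (is.null(tau_nm) || any(!is.finite(tau_nm))) {
    stop(sprintf("missing %s membrane thickness", toupper(membrane)),
         call. = FALSE)
  }
  sum(p * (tau_nm / 1000)) * stack$thickness
}

#' Periplasm volume by subtraction
#'
#' The default `table_consistent` mode subtracts cytoplasm and both
#' membrane shells from the whole-cell volume, which keeps the four
#' compartments additive. `text_literal` subtracts only the cytoplasm (so
#' the "periplasm" then includes both membranes). Negative results are
#' clamped to zero with a warning (possible under measurement noise).
#'
#' @param vol_whole,vol_cytoplasm,vol_om,vol_pm compartment volumes, fl.
#' @param mode `"table_consistent"` (default) or `"text_literal"`.
#' @return periplasm volume, fl.
#' @export
periplasm_volume <- function(vol_whole, vol_cytoplasm, vol_om = 0, vol_pm = 0,
                             mode = c("table_consistent", "text_literal")) {
  mode <- match.arg(mode)
  v <- if (mode == "table_consistent") {
    vol_whole - vol_cytoplasm - vol_om - vol_pm
  } else {
    vol_whole - vol_cytoplasm
  }
  if (any(v < 0)) {
    warning("negative periplasm volume clamped to 0", call. = FALSE)
    v <- pmax(v, 0)
  }
  v
}

#' Total ribosome count of a cell
#'
#' @param stack a `section_stack` with per-section ribosome counts.
#' @return integer total.
#' @export
ribosome_total <- function(stack) {
  stopifnot(inherits(stack, "section_stack"))
  counts <- stack$sections$ribosomes
  if (any(!is.finite(counts))) stop("missing ribosome counts", call. = FALSE)
  if (any(counts < 0)) stop("negative ribosome count", call. = FALSE)
  as.integer(round(sum(counts)))
}

#' Ribosome density per 0.1 fl of cytoplasm
#'
#' @param total total ribosome count.
#' @param vol_cytoplasm cytoplasmic volume, fl; must be positive.
#' @param round_to `"none"` (default) for full precision or `"nearest_10"`
#'   for the reporting convention (densities printed as multiples of 10).
#' @return density, count per 0.1 fl.
#' @export
ribosome_density <- function(total, vol_cytoplasm,
                             round_to = c("none", "nearest_10")) {
  round_to <- match.arg(round_to)
  if (any(vol_cytoplasm <= 0)) {
    stop("'vol_cytoplasm' must be positive", call. = FALSE)
  }
  d <- total / vol_cytoplasm * 0.1
  if (round_to == "nearest_10") d <- round_to_10(d)
  d
}

#' Quantify one cell: section stack to structome profile
#'
#' Composes all stereology estimators into the per-cell profile: length,
#' OM/PM diameters, aspect ratio, trapezoid surface areas, Cavalieri
#' volumes, membrane shells, periplasm by subtraction, and ribosome total
#' and density. All internal computation is at full precision; apply
#' [round_profile_table()] for report tables.
#'
#' @param stack a `section_stack`.
#' @param length_mode,length_um see [cell_length()].
#' @param diameter_estimator see [cell_diameter()].
#' @param periplasm_mode see [periplasm_volume()].
#' @param shell_thickness_nm optional list with elements `om` and/or `pm`
#'   overriding per-section membrane thicknesses.
#' @return a [cell_profile] row.
#' @export
#' @examples
#' m <- spherocylinder_model("demo")
#' st <- place_ribosomes(m, slice_model(m))
#' quantify_cell(st)
quantify_cell <- function(stack,
                          length_mode = c("section_count", "supplied"),
                          length_um = stack$length_um,
                          diameter_estimator = c("median_central", "mean_all",
                                                 "max"),
                          periplasm_mode = c("table_consistent",
                                             "text_literal"),
                          shell_thickness_nm = NULL) {
  stopifnot(inherits(stack, "section_stack"))
  length_mode <- match.arg(length_mode)
  diameter_estimator <- match.arg(diameter_estimator)
  periplasm_mode <- match.arg(periplasm_mode)

  n <- nrow(stack$sections)
  len <- cell_length(stack, mode = length_mode, length_um = length_um)
  d_om <- cell_diameter(stack, "om", diameter_estimator)
  d_pm <- cell_diameter(stack, "pm", diameter_estimator)
  vol_whole <- compartment_volume(stack, "om")
  vol_cyto <- compartment_volume(stack, "pm")
  vol_om <- shell_volume(stack, "om", thickness_nm = shell_thickness_nm$om)
  vol_pm <- shell_volume(stack, "pm", thickness_nm = shell_thickness_nm$pm)
  total <- ribosome_total(stack)
  new_cell_profile(
    cell_id = stack$cell_id,
    n_sections = n,
    length = len,
    diam_om = d_om,
    diam_pm = d_pm,
    aspect_ratio = aspect_ratio(len, d_om),
    surf_om = surface_area(stack, "om"),
    surf_pm = surface_area(stack, "pm"),
    vol_whole = vol_whole,
    vol_om = vol_om,
    vol_periplasm = periplasm_volume(vol_whole, vol_cyto, vol_om, vol_pm,
                                     mode = periplasm_mode),
    vol_pm = vol_pm,
    vol_cytoplasm = vol_cyto,
    ribosomes_total = total,
    ribosome_density = ribosome_density(total, vol_cyto)
  )
}

#' Quantify several stacks into a profile table
#'
#' @param stacks a list of `section_stack` objects.
#' @param ... passed on to [quantify_cell()].
#' @return a profile table (one [cell_profile] row per stack).
#' @export
quantify_cells <- function(stacks, ...) {
  if (inherits(stacks, "section_stack")) stacks <- list(stacks)
  do.call(rbind, lapply(stacks, quantify_cell, ...))
}
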