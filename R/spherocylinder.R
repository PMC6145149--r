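#' Synthetic spherocylinder cell model
#'
#' Defines an idealised rod-shaped bacterium: a cylinder capped by two
#' hemispheres, with the outer membrane (OM) as the outermost surface and
#' the plasma membrane (PM) set inwards by the envelope width. All
#' downstream stereology estimators can be validated against this model
#' because its surface areas and compartment volumes have closed forms
#' (see [analytic_truth()]).
#'
#' Defaults describe a typical exponential-phase *M. smegmatis* cell as
#' measured on serial ultrathin sections: OM diameter 0.58 um, length
#' 3.54 um, PM diameter 0.55 um (envelope width 0.015 um), and a
#' cytoplasmic ribosome density of 1170 per 0.1 fl.
#'
#' @param cell_id character label for the cell.
#' @param radius_om outer radius of the OM, um.
#' @param length_om pole-to-pole length, um; must be at least `2 * radius_om`.
#' @param envelope_width radial distance from the OM outer surface to the PM
#'   outer surface (OM thickness plus periplasm width), um.
#' @param pm_thickness plasma-membrane thickness, um.
#' @param om_thickness outer-membrane thickness, um.
#' @param ribosome_density true cytoplasmic ribosome density, count per
#'   0.1 fl of cytoplasm (1 fl = 1 um^3).
#' @param seed integer used as the default random seed by [slice_model()]
#'   and [place_ribosomes()] when they are not given one explicitly.
#' @return an object of class `"spherocylinder_model"`.
#' @seealso [cross_section()], [slice_model()], [place_ribosomes()],
#'   [analytic_truth()]
#' @export
#' @examples
#' m <- spherocylinder_model("cell-1")
#' analytic_truth(m)
spherocylinder_model <- function(cell_id = "synthetic",
                                 radius_om = 0.29,
                                 length_om = 3.54,
                                 envelope_width = 0.015,
                                 pm_thickness = 0.006,
                                 om_thickness = 0.002,
                                 ribosome_density = 1170,
                                 seed = 1L) {
  stopifnot_scalar_number(radius_om, "radius_om", 0, strict = TRUE)
  stopifnot_scalar_number(length_om, "length_om", 0, strict = TRUE)
  stopifnot_scalar_number(envelope_width, "envelope_width", 0)
  stopifnot_scalar_number(pm_thickness, "pm_thickness", 0)
  stopifnot_scalar_number(om_thickness, "om_thickness", 0)
  stopifnot_scalar_number(ribosome_density, "ribosome_density", 0)
  if (length_om < 2 * radius_om) {
    stop("'length_om' must be at least twice 'radius_om'", call. = FALSE)
  }
  if (envelope_width + pm_thickness <= 0) {
    stop("envelope_width + pm_thickness must be positive", call. = FALSE)
  }
  if (radius_om <= envelope_width + pm_thickness) {
    stop("'radius_om' must exceed envelope_width + pm_thickness", call. = FALSE)
  }
  if (om_thickness > envelope_width) {
    stop("'om_thickness' cannot exceed 'envelope_width'", call. = FALSE)
  }
  structure(
    list(
      cell_id = as.character(cell_id),
      radius_om = radius_om,
      length_om = length_om,
      envelope_width = envelope_width,
      pm_thickness = pm_thickness,
      om_thickness = om_thickness,
      ribosome_density = ribosome_density,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "spherocylinder_model"
  )
}

#' @export
print.spherocylinder_model <- function(x, ...) {
  cat("Spherocylinder cell model:", x$cell_id, "\n")
  cat(sprintf("  OM diameter %.3f um, length %.3f um (aspect %.2f)\n",
              2 * x$radius_om, x$length_om, x$length_om / (2 * x$radius_om)))
  cat(sprintf("  envelope width %.4f um (OM %.4f, PM %.4f um)\n",
              x$envelope_width, x$om_thickness, x$pm_thickness))
  cat(sprintf("  true ribosome density %g per 0.1 fl cytoplasm\n",
              x$ribosome_density))
  invisible(x)
}

# closed-form spherocylinder volume (fl = um^3) and surface area (um^2)
sc_volume <- function(r, L) pi * r^2 * (L - 2 * r) + (4 / 3) * pi * r^3
sc_surface <- function(r, L) 2 * pi * r * L

# squared radius profile of a spherocylinder with outer radius r spanning
# [z0, z0 + L] along the axis; vectorised, zero outside the extent
sc_radius2 <- function(z, r, z0, L) {
  z1 <- z0 + L
  c_lo <- z0 + r
  c_hi <- z1 - r
  r2 <- rep(0, length(z))
  mid <- z >= c_lo & z <= c_hi
  r2[mid] <- r^2
  lo <- z >= z0 & z < c_lo
  r2[lo] <- r^2 - (z[lo] - c_lo)^2
  hi <- z > c_hi & z <= z1
  r2[hi] <- r^2 - (z[hi] - c_hi)^2
  pmax(r2, 0)
}

# exact integral of the cross-sectional area pi * rho^2(z) of that
# spherocylinder over [a, b] (used for ribosome slab weights)
sc_slab_volume <- function(a, b, r, z0, L) {
  z1 <- z0 + L
  a <- pmax(a, z0)
  b <- pmin(b, z1)
  if (any(b <= a)) return(ifelse(b <= a, 0, NA_real_))
  c_lo <- z0 + r
  c_hi <- z1 - r
  # antiderivative pieces: cap about centre c has area pi*(r^2 - (z-c)^2)
  cap_int <- function(lo, hi, cc) {
    F <- function(z) pi * (r^2 * z - (z - cc)^3 / 3)
    F(hi) - F(lo)
  }
  seg <- 0
  lo1 <- pmin(pmax(a, z0), c_lo); hi1 <- pmin(b, c_lo)
  if (hi1 > lo1) seg <- seg + cap_int(lo1, hi1, c_lo)
  lo2 <- pmax(a, c_lo); hi2 <- pmin(b, c_hi)
  if (hi2 > lo2) seg <- seg + pi * r^2 * (hi2 - lo2)
  lo3 <- pmax(a, c_hi); hi3 <- pmin(b, z1)
  if (hi3 > lo3) seg <- seg + cap_int(lo3, hi3, c_hi)
  seg
}

#' Analytic cross-section of a spherocylinder model
#'
#' Evaluates the exact section geometry at axial positions `z` (um from one
#' pole): the OM and PM cross-section radii, perimeters and areas. Inside
#' the cylindrical mid-segment the OM radius equals `radius_om`; within a
#' cap at axial distance d from the cap's sphere centre it is
#' `sqrt(radius_om^2 - d^2)`; outside `[0, length_om]` all values are zero.
#'
#' @param model a [spherocylinder_model()].
#' @param z numeric vector of axial positions, um.
#' @return a data frame with one row per `z`: `axial_position`, `r_om`,
#'   `r_pm` (um), `p_om`, `p_pm` (perimeters, um), `a_om`, `a_pm`
#'   (cross-sectional areas, um^2).
#' @export
cross_section <- function(model, z) {
  stopifnot(inherits(model, "spherocylinder_model"))
  if (!is.numeric(z) || any(!is.finite(z))) {
    stop("'z' must be finite numeric", call. = FALSE)
  }
  w <- model$envelope_width
  r2_om <- sc_radius2(z, model$radius_om, 0, model$length_om)
  r2_pm <- sc_radius2(z, model$radius_om - w, w, model$length_om - 2 * w)
  r_om <- sqrt(r2_om)
  r_pm <- sqrt(r2_pm)
  data.frame(
    axial_position = z,
    r_om = r_om, r_pm = r_pm,
    p_om = 2 * pi * r_om, p_pm = 2 * pi * r_pm,
    a_om = pi * r2_om, a_pm = pi * r2_pm
  )
}

#' Slice a model cell into a serial-section measurement stack
#'
#' Emulates serial ultrathin sectioning: the cell (spanning `[0, L]`) is cut
#' by parallel planes `thickness` um apart, and each section that intersects
#' the cell yields one measurement row, evaluated at the section's
#' mid-plane. With `noise_cv > 0`, perimeters, areas and axis lengths are
#' multiplied by independent lognormal factors with unit mean and the given
#' coefficient of variation, mimicking tracing error.
#'
#' @param model a [spherocylinder_model()].
#' @param thickness section thickness, um (default 0.040, i.e. 40 nm).
#' @param offset axial offset of the first cutting plane below the cell's
#'   proximal pole, um; must lie in `[0, thickness)`.
#' @param noise_cv coefficient of variation of multiplicative measurement
#'   noise (0 = noise free).
#' @param seed integer seed; defaults to the model's own seed. `NULL` uses
#'   the current RNG stream.
#' @return a `section_stack`: a list with `cell_id`, `thickness`, `offset`
#'   and a `sections` data frame (one row per section, the measurement
#'   columns of the interchange format; `ribosomes` is 0 until
#'   [place_ribosomes()] fills it).
#' @export
slice_model <- function(model, thickness = 0.04, offset = 0, noise_cv = 0,
                        seed = model$seed) {
  stopifnot(inherits(model, "spherocylinder_model"))
  stopifnot_scalar_number(thickness, "thickness", 0, strict = TRUE)
  stopifnot_scalar_number(offset, "offset", 0)
  stopifnot_scalar_number(noise_cv, "noise_cv", 0)
  if (offset >= thickness) stop("'offset' must be < 'thickness'", call. = FALSE)
  L <- model$length_om
  n <- ceiling((L + offset) / thickness)
  k <- seq_len(n)
  z_lo <- (k - 1) * thickness - offset
  keep <- z_lo < L & (z_lo + thickness) > 0
  k <- k[keep]
  z_lo <- z_lo[keep]
  z_mid <- z_lo + thickness / 2
  geom <- cross_section(model, z_mid)

  sec <- data.frame(
    section_index = seq_along(k),
    p_om_um = geom$p_om, p_pm_um = geom$p_pm,
    a_om_um2 = geom$a_om, a_pm_um2 = geom$a_pm,
    minor_om_um = 2 * geom$r_om, major_om_um = 2 * geom$r_om,
    minor_pm_um = 2 * geom$r_pm, major_pm_um = 2 * geom$r_pm,
    ribosomes = 0L,
    om_thickness_nm = model$om_thickness * 1000,
    pm_thickness_nm = model$pm_thickness * 1000
  )
  if (noise_cv > 0) {
    noisy_cols <- c("p_om_um", "p_pm_um", "a_om_um2", "a_pm_um2",
                    "minor_om_um", "major_om_um", "minor_pm_um", "major_pm_um")
    sdlog <- sqrt(log(1 + noise_cv^2))
    sec[noisy_cols] <- with_local_seed(seed, {
      lapply(sec[noisy_cols], function(v) {
        v * stats::rlnorm(length(v), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      })
    })
  }
  new_section_stack(model$cell_id, thickness, sec, offset = offset)
}

#' Place ribosomes into a sliced synthetic cell
#'
#' Draws the cell's total ribosome count N from a Poisson distribution with
#' mean `density * cytoplasm volume / 0.1 fl`, then apportions N across
#' sections multinomially with probabilities proportional to each section's
#' exact cytoplasmic slab volume — equivalent to homogeneous (complete
#' spatial randomness) placement throughout the cytoplasm. Per-section
#' counts always sum to N exactly.
#'
#' @inheritParams slice_model
#' @param stack a `section_stack` produced by [slice_model()] from `model`.
#' @return the stack with its `ribosomes` column filled.
#' @export
place_ribosomes <- function(model, stack, seed = model$seed) {
  stopifnot(inherits(model, "spherocylinder_model"),
            inherits(stack, "section_stack"))
  if (model$ribosome_density < 0) stop("negative ribosome density", call. = FALSE)
  w <- model$envelope_width
  r_pm <- model$radius_om - w
  L_pm <- model$length_om - 2 * w
  v_cyto <- sc_volume(r_pm, L_pm)
  t <- stack$thickness
  offset <- if (is.null(stack$offset)) 0 else stack$offset
  z_lo <- (stack$sections$section_index - 1) * t - offset
  slab <- vapply(z_lo, function(a) {
    sc_slab_volume(a, a + t, r_pm, w, L_pm)
  }, numeric(1))
  counts <- with_local_seed(seed, {
    n_total <- stats::rpois(1, model$ribosome_density * v_cyto / 0.1)
    if (n_total == 0 || sum(slab) <= 0) {
      rep(0L, length(slab))
    } else {
      as.integer(stats::rmultinom(1, n_total, prob = slab / sum(slab)))
    }
  })
  stack$sections$ribosomes <- counts
  stack
}

#' Exact structome profile of a model cell
#'
#' Closed-form ground truth for every per-cell metric the stereology
#' estimators compute from sections: for a spherocylinder of radius r and
#' length L, volume is `pi r^2 (L - 2r) + (4/3) pi r^3` and surface area
#' `2 pi r (L - 2r) + 4 pi r^2 = 2 pi r L`. Membrane shell volumes are
#' differences of nested spherocylinders; the periplasm is the whole-cell
#' volume minus cytoplasm and both membrane shells. The reported ribosome
#' total is the expected (not sampled) count.
#'
#' @param model a [spherocylinder_model()].
#' @return a [cell_profile] row with the exact values.
#' @export
analytic_truth <- function(model) {
  stopifnot(inherits(model, "spherocylinder_model"))
  r_om <- model$radius_om
  L <- model$length_om
  w <- model$envelope_width
  r_pm <- r_om - w
  L_pm <- L - 2 * w
  t_om <- model$om_thickness
  t_pm <- model$pm_thickness
  vol_whole <- sc_volume(r_om, L)
  vol_cyto <- sc_volume(r_pm, L_pm)
  vol_om <- vol_whole - sc_volume(r_om - t_om, L - 2 * t_om)
  vol_pm <- vol_cyto - sc_volume(r_pm - t_pm, L_pm - 2 * t_pm)
  total <- model$ribosome_density * vol_cyto / 0.1
  new_cell_profile(
    cell_id = model$cell_id,
    n_sections = NA_integer_,
    length = L,
    diam_om = 2 * r_om,
    diam_pm = 2 * r_pm,
    aspect_ratio = L / (2 * r_om),
    surf_om = sc_surface(r_om, L),
    surf_pm = sc_surface(r_pm, L_pm),
    vol_whole = vol_whole,
    vol_om = vol_om,
    vol_periplasm = vol_whole - vol_cyto - vol_om - vol_pm,
    vol_pm = vol_pm,
    vol_cytoplasm = vol_cyto,
    ribosomes_total = total,
    ribosome_density = model$ribosome_density
  )
}

#' Simulate section stacks for a set of model cells
#'
#' Convenience wrapper: slices each model and places ribosomes, deriving a
#' reproducible sub-seed per cell from `seed`.
#'
#' @param models a list of [spherocylinder_model()] objects (or a single one).
#' @inheritParams slice_model
#' @return a list of `section_stack` objects, one per model.
#' @export
simulate_section_stacks <- function(models, thickness = 0.04, offset = 0,
                                    noise_cv = 0, seed = 1L) {
  if (inherits(models, "spherocylinder_model")) models <- list(models)
  stopifnot(length(models) >= 1)
  sub_seeds <- with_local_seed(seed, sample.int(.Machine$integer.max - 1L,
                                                2L * length(models)))
  lapply(seq_along(models), function(i) {
    m <- models[[i]]
    st <- slice_model(m, thickness = thickness, offset = offset,
                      noise_cv = noise_cv, seed = sub_seeds[2 * i - 1])
    place_ribosomes(m, st, seed = sub_seeds[2 * i])
  })
}
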