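# Builders for hand-made section stacks used across the test files.

# A stack with explicitly given per-section perimeters/areas; everything
# else defaults to consistent filler values.
make_stack <- function(p_om, thickness = 0.04,
                       p_pm = p_om * 0.95,
                       a_om = (p_om / (2 * pi))^2 * pi,
                       a_pm = (p_pm / (2 * pi))^2 * pi,
                       ribosomes = rep(0L, length(p_om)),
                       om_thickness_nm = 2, pm_thickness_nm = 6,
                       cell_id = "test", length_um = NULL) {
  n <- length(p_om)
  sec <- data.frame(
    section_index = seq_len(n),
    p_om_um = p_om, p_pm_um = p_pm,
    a_om_um2 = a_om, a_pm_um2 = a_pm,
    minor_om_um = p_om / pi, major_om_um = p_om / pi,
    minor_pm_um = p_pm / pi, major_pm_um = p_pm / pi,
    ribosomes = ribosomes,
    om_thickness_nm = om_thickness_nm, pm_thickness_nm = pm_thickness_nm
  )
  new_section_stack(cell_id, thickness, sec, length_um = length_um)
}

# Sections of an ideal cylinder of length L and cross-sectional area a,
# cut at thickness t and measured at mid-planes (area zero where the
# mid-plane falls beyond the cylinder).
make_cylinder_stack <- function(L, t, a = 0.25) {
  n <- ceiling(L / t)
  z_mid <- (seq_len(n) - 0.5) * t
  areas <- ifelse(z_mid < L, a, 0)
  p <- ifelse(z_mid < L, 2 * sqrt(pi * a), 0)
  make_stack(p_om = p, thickness = t, a_om = areas,
             p_pm = p, a_pm = areas)
}

expect_rel_error_lt <- function(est, truth, tol) {
  expect_lt(abs(est - truth) / abs(truth), tol)
}
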