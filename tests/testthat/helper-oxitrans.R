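# Shared fixtures: all synthetic, built in code.

obi <- standard_oxime_pair("obidoxime-paraoxon")
hi6 <- standard_oxime_pair("hi6-sarin")

default_grid <- c(15, 30, 45, 60)

# Noiseless Ellman time course generated from a known rate.
make_timecourse <- function(kobs, t = default_grid, v_c = 1, v_i = 0.1) {
  tibble::tibble(t = t, v_t = reactivation_velocity(kobs, t, v_c, v_i))
}

# Printed transport-difference cells that are arithmetically self-consistent
# with their tables' concentration columns (ratio-of-means convention).
# Cells whose printed value contradicts its own concentrations are excluded;
# the Table 2 NP-PEG 0.26/100 cell is printed without its minus sign and is
# asserted with the sign restored.
consistent_diff_cells <- function() {
  tibble::tribble(
    ~table_id, ~carrier,  ~particle_load_mg_cm2, ~loading_dose_uM, ~printed_diff,
    1, "NP-ApoE", 0.52,  100,   39.06,
    1, "NP-PEG",  0.52,  100,   20.13,
    1, "NP-ApoE", 0.52, 1000,  133.49,
    1, "NP-PEG",  0.52, 1000,   60.64,
    1, "NP-ApoE", 0.26,  100,  -32.44,
    1, "NP-PEG",  0.26,  100,  -48.40,
    1, "NP-ApoE", 0.26, 1000,  123.48,
    1, "NP-PEG",  0.26, 1000,   73.33,
    2, "NP-ApoE", 0.52,  100,   41.46,
    2, "NP-PEG",  0.52,  100,   -4.39,
    2, "NP-ApoE", 0.52, 1000,  136.73,
    2, "NP-PEG",  0.52, 1000,   77.02,
    2, "NP-ApoE", 0.26,  100,   -3.89,
    2, "NP-PEG",  0.26,  100,  -80.25,
    2, "NP-ApoE", 0.26, 1000,  100.68,
    3, "NP-ApoE", 0.52,  100,  193.76,
    3, "NP-PEG",  0.52,  100,   36.51,
    3, "NP-ApoE", 0.52, 1000,  193.16,
    3, "NP-PEG",  0.52, 1000,   41.81,
    3, "NP-ApoE", 0.26,  100,  143.50
  )
}
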