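# Calibrated four-stage rat tongue cohort.
# mean_g / between_sd: published group means +/- SD (G-value).
# within_sd: published within-sample SD of a 200-px measurement line.
# axial_slope / slope_sd: apex->root gradient statistics per group.
# spot_*: dark-spot field tuned so pooled pixel ranges approximate the
#   published per-group ranges (Control 17.4, LGD 39.1, HGD/CIS 56.1,
#   Cancer 40.2) while keeping the variance decomposition feasible.
model: rat
n_points: 200
height: 64
stages:
  Control:
    mean_g: 32.5
    between_sd: 3.2
    within_sd: 2.43
    axial_slope: 0.03
    slope_sd: 0.01
    spot_rate: 0
    spot_depth: 0
    spot_width: 3
    n_animals: 10
  LGD:
    mean_g: 54.6
    between_sd: 7.5
    within_sd: 3.79
    axial_slope: -0.03
    slope_sd: 0.03
    spot_rate: 0.5
    spot_depth: 8
    spot_width: 3
    n_animals: 11
  HGD_CIS:
    mean_g: 46.1
    between_sd: 6.2
    within_sd: 3.68
    axial_slope: 0.002
    slope_sd: 0.04
    spot_rate: 1.0
    spot_depth: 8
    spot_width: 3
    n_animals: 15
  Cancer:
    mean_g: 49.1
    between_sd: 7.1
    within_sd: 4.42
    axial_slope: -0.03
    slope_sd: 0.04
    spot_rate: 1.5
    spot_depth: 9
    spot_width: 3
    n_animals: 14
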