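# Human tongue application: four measurement sites from one patient,
# 50-pixel lines. Site means from the clinical measurements; within_sd from
# the human sample-SD row. Single site per stage -> no between-site SD, no
# imposed axial gradient, no spot field (the wide Cancer distribution is
# carried entirely by within_sd).
model: human
n_points: 50
height: 64
stages:
  Control:
    mean_g: 37.4
    between_sd: 0
    within_sd: 1.34
    axial_slope: 0
    n_animals: 1
  LGD:
    mean_g: 40.6
    between_sd: 0
    within_sd: 4.72
    axial_slope: 0
    n_animals: 1
  HGD_CIS:
    mean_g: 44.1
    between_sd: 0
    within_sd: 3.74
    axial_slope: 0
    n_animals: 1
  Cancer:
    mean_g: 36.2
    between_sd: 0
    within_sd: 10.59
    axial_slope: 0
    n_animals: 1
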