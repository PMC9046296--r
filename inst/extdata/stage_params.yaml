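# Default per-stage simulation parameters for the synthetic chondrocyte
# dedifferentiation model.
#
# These values are ILLUSTRATIVE, NOT MEASURED. They encode only the ordinal
# structure of the biphasic model: RBP4/SOD3 intensity peaks mid-culture
# (P2); IFITM3 and F-actin intensity rise monotonically with passage; cell
# and nucleus diameters grow with passage; late stages are more elongated
# (fibroblast-like). Intensities are arbitrary fluorescence units, diameters
# in micrometres.
version: 1
size_correlation: 0.6      # cell vs nucleus diameter correlation, in [0, 1)
aspect_ratio_min: 1.0
stages:
  P0:
    rbp4_mean: 60.0
    sod3_mean: 50.0
    ifitm3_mean: 30.0
    factin_mean: 40.0
    rbp4_cv: 0.25
    sod3_cv: 0.25
    ifitm3_cv: 0.25
    factin_cv: 0.25
    cell_diameter_mean: 18.0
    cell_diameter_sd: 2.0
    nucleus_diameter_mean: 9.0
    nucleus_diameter_sd: 1.0
    aspect_ratio_max: 1.4
  P2:
    rbp4_mean: 120.0
    sod3_mean: 110.0
    ifitm3_mean: 55.0
    factin_mean: 70.0
    rbp4_cv: 0.25
    sod3_cv: 0.25
    ifitm3_cv: 0.25
    factin_cv: 0.25
    cell_diameter_mean: 22.0
    cell_diameter_sd: 2.5
    nucleus_diameter_mean: 10.5
    nucleus_diameter_sd: 1.2
    aspect_ratio_max: 1.6
  P4:
    rbp4_mean: 70.0
    sod3_mean: 65.0
    ifitm3_mean: 90.0
    factin_mean: 110.0
    rbp4_cv: 0.25
    sod3_cv: 0.25
    ifitm3_cv: 0.25
    factin_cv: 0.25
    cell_diameter_mean: 28.0
    cell_diameter_sd: 3.0
    nucleus_diameter_mean: 13.0
    nucleus_diameter_sd: 1.5
    aspect_ratio_max: 1.9
  P8:
    rbp4_mean: 40.0
    sod3_mean: 35.0
    ifitm3_mean: 140.0
    factin_mean: 160.0
    rbp4_cv: 0.25
    sod3_cv: 0.25
    ifitm3_cv: 0.25
    factin_cv: 0.25
    cell_diameter_mean: 34.0
    cell_diameter_sd: 3.5
    nucleus_diameter_mean: 16.0
    nucleus_diameter_sd: 1.8
    aspect_ratio_max: 2.2
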