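# Frozen reference values for the published 27-configuration design table of
# the 48-drug x 4-dilution instrument. Count columns are exact integers; the
# two time columns are kept as printed strings so their precision is known.
# The printed radial count at (r=4, n_rad=40) is malformed in the source
# table ("91,06440") and stored as NA; tests assert the formula value
# 9,106,440 there. The printed full-screen time at (r=3, n_rad=48) is 0.5,
# inconsistent with its own position count (6624 positions -> 0.767 days);
# tests assert the model value and flag the row.
reference_design_table <- function() {
  df <- read.csv(text = '
r,n_rad,n_combinations,n_meaningful,n_circ,n_radial,n_positions,time,time_ml
2,2,6,4,2,2,2,0.0002,0.000001
2,3,15,12,6,6,4,0.0004,0.000003
2,4,28,24,12,12,6,0.0007,0.000007
2,6,66,60,30,30,10,0.001,0.00002
2,8,120,112,56,56,14,0.002,0.00003
2,10,190,180,90,90,18,0.002,0.00005
2,20,780,760,380,380,38,0.004,0.0002
2,30,1770,1740,870,870,58,0.007,0.0005
2,48,4560,4512,2256,2256,94,0.01,0.0014
3,3,84,27,3,24,9,0.001,0.000002
3,4,220,96,12,84,24,0.003,0.000007
3,6,816,432,60,372,72,0.008,0.00004
3,8,2024,1152,168,984,144,0.02,0.0001
3,10,4060,2400,360,2040,240,0.03,0.0002
3,20,34220,21600,3420,18180,1080,0.13,0.0021
3,30,117480,75600,12180,63420,2520,0.3,0.0073
3,40,280840,182400,29640,152760,4560,0.5,0.0179
3,48,487344,317952,51888,266064,6624,0.5,0.0313
4,4,1820,256,4,252,64,0.007,0.000002
4,6,10626,2592,60,2532,432,0.05,0.00003
4,8,35960,10240,280,9960,1280,0.15,0.0002
4,10,91390,28000,840,27160,2800,0.3,0.0005
4,20,1581580,544000,19380,524620,27200,3.15,0.0117
4,30,8214570,2916000,109620,2806380,97200,11.3,0.0661
4,35,15329615,5488000,209440,5278560,156800,18.1,0.1263
4,40,26294360,9472000,365560,NA,236800,27.4,0.2204
4,48,54870480,19906560,778320,19128240,414720,48,0.4692
', colClasses = c(rep("numeric", 7), "character", "character"),
    strip.white = TRUE)
  df
}

# half a unit in the last printed decimal place of a value given as string
half_ulp <- function(s) {
  dec <- ifelse(grepl("\\.", s), nchar(sub(".*\\.", "", s)), 0L)
  0.5 * 10^-dec
}

# rows where the printed full-screen time disagrees with the position count
# by more than half a printed unit (documented table inconsistencies)
time_exception_rows <- function(ref)
  which((ref$r == 3 & ref$n_rad == 48) | (ref$r == 2 & ref$n_rad == 3))

dilution_cfg <- function(r, n_rad)
  instrument_config(n_rings = r, n_radii = n_rad, combo_order = r,
                    n_dilutions = r)
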