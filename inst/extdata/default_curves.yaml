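# Default suitability-index breakpoints for the eight model variables.
# Each curve maps an environmental value (x, variable units) to a
# suitability index (si, 0-1) by linear interpolation; outside the listed
# span the curve clamps to its edge value unless policy is "zero".
# These are documented approximations of published suitability shapes for
# subtropical intertidal rock oysters; replace with study-specific curves
# where available.
Ss:              # salinity at larval settlement (ppt)
  x:  [0, 5, 10, 15, 20, 30, 35, 40]
  si: [0, 0.05, 0.5, 0.9, 1, 1, 0.8, 0.5]
V:               # water flow velocity (m/s); turbulent flows limit settlement
  x:  [0, 0.2, 0.8, 1.5, 2.5, 3]
  si: [0.4, 1, 1, 0.5, 0.1, 0]
T:               # water temperature (degrees C), oxygen-consumption optimum
  x:  [10, 15, 20, 25, 30, 35, 40]
  si: [0, 0.3, 0.7, 1, 1, 0.4, 0]
S_G:             # salinity for growth (ppt), respiration-derived
  x:  [0, 5, 10, 15, 20, 25, 30, 35]
  si: [0, 0.1, 0.4, 0.6, 0.8, 1, 1, 0.9]
pH:              # water pH, optimum near 7.9-8.5
  x:  [6.5, 7, 7.5, 7.9, 8.5, 9]
  si: [0, 0.2, 0.6, 1, 1, 0.3]
DO:              # dissolved oxygen (% saturation)
  x:  [0, 20, 40, 60, 80, 100]
  si: [0, 0.1, 0.4, 0.8, 1, 1]
PIM:             # particulate inorganic matter (mg/L); high loads impair feeding
  x:  [0, 100, 300, 500, 700, 1100]
  si: [1, 1, 0.8, 0.5, 0.3, 0.1]
Chla:            # chlorophyll-a (ug/L), food availability proxy
  x:  [0, 1, 3, 5, 10]
  si: [0, 0.4, 0.8, 1, 1]
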