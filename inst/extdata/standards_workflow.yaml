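# Reference-standard identification workflow.
# Stage methods come from the package registry (see lcmspipe::list_stages());
# a parameter may carry per-ion-mode variants (positive:/negative:), picked
# per sample from its mzML polarity.
stages:
  - name: read
    method: read_mzml
  - name: centroid
    method: centroid
  - name: threshold
    method: intensity_threshold
    params:
      min_intensity: 500
  - name: extract
    method: extract
    params:
      tol_ppm: 10
      min_intensity: 2000
  - name: width
    method: width_filter
    params:
      min_scans: 4
  - name: deconvolve
    method: deconvolve
  - name: group
    method: group
  - name: isotopes
    method: isotopes
  - name: adducts
    method: adducts
    params:
      rules:
        positive: adducts_positive.csv
        negative: adducts_negative.csv
  - name: match
    method: match
    params:
      library: reference_library.csv
      rules:
        positive: adducts_positive.csv
        negative: adducts_negative.csv
      tol_ppm: 5
      rt_tol: 10
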