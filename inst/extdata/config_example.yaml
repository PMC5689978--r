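# Example pipeline configuration. File paths are resolved relative to this
# file; omit a section to use the shipped defaults.
calibration:
  # file: my_calibration.csv     # columns: hu, density
binning:
  enabled: true
  # file: my_bins.csv            # columns: low, high, representative
tissue:
  # file: my_tissues.csv         # columns: low, high, name, <element symbols>
source:
  id: mHDR-v2
tallies:
  nps: 1000000
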