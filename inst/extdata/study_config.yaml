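# Example study configuration for the echotype CLI.
# partition_file is resolved relative to this file when not absolute.
partition_file: canonical_partition.yaml
reference_level: 200
classification:
  decision_margin: 0.05
  lake_threshold: 0.25
  class_ranges:
    VEG: ["hypoechogenic IV", "echogenic III"]
    LEG: ["hypoechogenic II", "echogenic I"]
    MEG: ["hypoechogenic III", "echogenic II"]
    NEG: ["echogenic II", "hyperechogenic I"]
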