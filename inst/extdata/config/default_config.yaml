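# Default pipeline configuration. Every tunable the pipeline consumes lives
# here so a run manifest (config echo + seed) reproduces any report.
profiles:
  hydrophilicity_scale: hopp-woods     # kyte-doolittle selectable; it is negated
                                       # on load so high = hydrophilic everywhere
  hydrophilicity_window: 7
  flexibility_window: 7
  flexibility_weights: [0.25, 0.4375, 0.625, 1.0, 0.625, 0.4375, 0.25]
  surface_anchor: first                # hexapeptide value anchored to first residue
  edge_policy: mask                    # or shrink
secstruct:
  helix_former_cutoff: 1.03
  strand_former_cutoff: 1.05
  turn_tetrapeptide_cutoff: 0.000075
  extension_floor: 1.00
  tie_break: ["T", "C", "E", "H"]
antigenic_index:
  score_levels: [-0.6, -0.3, -0.1, 0.0, 0.1, 0.3, 0.6]
  hydrophilicity_thresholds: [-2.0, -1.0, -0.5, 0.0, 0.5, 1.5]
  surface_thresholds: [0.25, 0.5, 0.75, 1.0, 2.0, 5.0]
  flexibility_thresholds: [0.93, 0.96, 0.99, 1.0, 1.03, 1.06]
  structure_scores: {"H": -0.6, "E": -0.3, "C": 0.3, "T": 0.6}
  weights:
    hydrophilicity: 0.3
    surface: 0.15
    flexibility: 0.15
    cf_structure: 0.2
    gr_structure: 0.2
selection:
  min_length: 8
  ai_threshold: 0.15
  hydrophilicity_min: 0.25
  surface_min: 1.0
  flexibility_min: 1.0
  max_rigid_fraction: 0.3
  gap_merge: 2
  forbidden_regions: []                # list of [start, end], 1-based inclusive
  rank_weights: [1.0, 1.0, 1.0, 1.0]   # ai, hydrophilicity, surface, flexibility
conservation:
  gap_policy: exclude                  # or count-as-mismatch
  variable_identity_threshold: 1.0
  aligner: {match: 1, mismatch: -1, gap: -2}
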