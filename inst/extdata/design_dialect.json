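{
  "description": "Native design-bundle dialect: four RFC-4180 CSV tables plus a JSON header. Adapt external (j5-style) exports with a column mapping of the same shape (see design_dialect()).",
  "files": {
    "parts": "parts.csv",
    "oligos": "oligos.csv",
    "fragments": "fragments.csv",
    "constructs": "constructs.csv",
    "meta": "design.json"
  },
  "columns": {
    "parts": {
      "part_id": "unique part identifier",
      "bin_id": "combinatorial bin the part belongs to",
      "role": "vector | insert",
      "sequence": "uppercase ACGT, includes flanking homology arms"
    },
    "oligos": {
      "oligo_id": "unique oligo identifier",
      "name": "vendor-facing name",
      "sequence": "10..60 nt"
    },
    "fragments": {
      "fragment_id": "unique PCR-product identifier",
      "part_id": "part the fragment amplifies",
      "length_bp": "product length including homology arms",
      "left_overlap_bp": "homology shared with the upstream neighbor",
      "right_overlap_bp": "homology shared with the downstream neighbor",
      "template_id": "PCR template stock identifier",
      "forward_oligo_id": "forward primer",
      "reverse_oligo_id": "reverse primer"
    },
    "constructs": {
      "construct_id": "unique target-construct identifier",
      "fragment_ids": "semicolon-joined ordered fragment list (>= 2)",
      "circular": "TRUE for plasmids (default), FALSE for linear"
    },
    "meta": {
      "design_id": "design identifier",
      "homology_bp": "campaign minimum junction overlap",
      "oligo_max_nt": "vendor oligo length limit"
    }
  },
  "notes": "Unknown columns are preserved as opaque metadata (e.g. annealing_c on fragments). Row order is never semantically significant."
}
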