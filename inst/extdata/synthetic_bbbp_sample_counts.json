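{
  "n_input": 48,
  "n_nitrogen_fixed": 2,
  "n_unparseable_dropped": 1,
  "n_duplicates_removed": 5,
  "n_triplicate_groups": 1,
  "n_inconsistent_records_removed": 2,
  "note": "synthetic stand-in for the public BBBP benchmark; defects injected with known counts"
}
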