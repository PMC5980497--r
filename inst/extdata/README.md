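# Bundled example data

- `north_synthetic_47.csv` — a SYNTHETIC stand-in for a northern
  temperate-forest calibration occurrence set: 47 presence records
  constructed to occupy 42 distinct cells of the global 2.5-arc-minute
  grid anchored at (-180, -90), so grid thinning reduces 47 records to
  42. The coordinates are generated, not field records of any species;
  the file exists to exercise the occurrence-thinning machinery at a
  realistic size and location.
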