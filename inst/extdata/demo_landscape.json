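{
  "chromosomes": [
    {"name": "chr1", "length": 8000000},
    {"name": "chr2", "length": 8000000}
  ],
  "chromatin": [
    {"chrom": "chr1", "start": 0, "end": 3000000, "class": "euchromatic"},
    {"chrom": "chr1", "start": 3000000, "end": 5000000, "class": "heterochromatic"},
    {"chrom": "chr1", "start": 5000000, "end": 8000000, "class": "euchromatic"},
    {"chrom": "chr2", "start": 0, "end": 3000000, "class": "euchromatic"},
    {"chrom": "chr2", "start": 3000000, "end": 5000000, "class": "heterochromatic"},
    {"chrom": "chr2", "start": 5000000, "end": 8000000, "class": "euchromatic"}
  ],
  "hotspots": [
    {"chrom": "chr1", "center": 1500000, "width": 200000, "peak_rate": 50},
    {"chrom": "chr2", "center": 6500000, "width": 200000, "peak_rate": 50}
  ],
  "background_rates": {"euchromatic": 5.076, "heterochromatic": 0.286}
}
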