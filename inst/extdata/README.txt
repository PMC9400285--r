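kir_regions_synthetic.bed
  SYNTHETIC stand-in region file for the 15 KIR genes: evenly spaced 10 kb
  intervals within the chr19q13.4 KIR locus neighbourhood, in BED 0-based
  half-open coordinates (chrom, start, end, gene). These are NOT verified
  gene coordinates. For real data, supply a BED of authoritative KIR gene
  coordinates matched to the reference build your BAM/CRAM was aligned to.
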