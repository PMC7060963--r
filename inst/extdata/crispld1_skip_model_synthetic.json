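{
  "_comment": "Synthetic transcript model of the edited CRISPLD1 allele. Only the combined coding length of exons 6-8 (303 nt, lost by exon skipping) is reported; the per-exon split used here (117/96/90 nt) is an invented partition that preserves that total and is labelled synthetic for that reason.",
  "transcript_id": "CRISPLD1_synthetic",
  "exons": [[5, 120], [6, 117], [7, 96], [8, 90], [9, 141]],
  "cds_frame_offset": 0
}
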