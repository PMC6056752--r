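# Sidecar annotations for synthetic_fusion_proteins.fasta, keyed by FASTA
# record id. Both records are synthetic toy stand-ins: short sequences that
# reproduce the structural features the selection rules react to (signature
# peptides, disulfide cysteines, a shared Fc-like tail, N-terminal variants),
# not the real therapeutic sequences.
ETN_SYN:
  name: synthetic Etanercept-like Fc-fusion
  disulfide_cys_positions: [18, 26]
  fusion_junction: 43
ABT_SYN:
  name: synthetic Abatacept-like Fc-fusion
  disulfide_cys_positions: [21]
  fusion_junction: 39
  alternative_starts:
    drugbank: ""
    review: "A"
    kegg: "MA"
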