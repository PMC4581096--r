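benchmark10_synthetic.tsv
  Synthetic 10-node, 11-edge benchmark DAG constructed for this package
  (fan-out hub -> cascade -> collider motifs). Not a published topology.

raf_pathway_reconstructed_edges.tsv
  Directed edge list (source<TAB>target) of the Raf signalling pathway,
  reconstructed from consensus descriptions in the signalling literature.
  Published versions differ in a few edges; treat as approximate.
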