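# Small synthetic two-cohort study; node and cohort sizes are reduced so
# the example runs in seconds. Drop the generator section and add
# paths: {node_table: ..., manifest: ...} to analyse a real study.
generator:
  n_nodes: 40
  n_msni: 5
  n_msci: 7
  decay_length: 100
  seed: 42
idleness: 0.5
ground_metric: hop
measures: [strength, betweenness, clustering, curvature]
alpha: 0.05
do_global: true
small_worldness: false
global_directions:
  characteristic_path_length: msci_greater
  diameter: msci_greater
correct_correlations: false
seed: 42
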