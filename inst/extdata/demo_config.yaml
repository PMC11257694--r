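# Demonstration pipeline configuration: a 12-node, 3-module synthetic
# system, 10 subjects in each of 2 conditions, with a coupling reduction
# planted on the coupling among regions 1-3 in the second condition.
n_nodes: 12
module_sizes: [4, 4, 4]
within_coupling: 0.2
between_coupling: 0.05
noise_corr_within: 0.3
n_subjects: 10
conditions: [baseline, effect]
design: paired
effect_edges:
  - [1, 2]
  - [1, 3]
  - [2, 3]
effect_scale: 0.3
n_timepoints: 600
tau: 1
measures: [synergy, redundancy, phi_r]
workspace_rule: sign
threshold: 9
alpha: 0.05
n_perm: 1000
component_measure: intensity
seed: 2024
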