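ROS:
  role: input
Abeta:
  role: output
  phenotype: Abeta
ptau:
  role: output
  phenotype: ptau
synapse_loss:
  role: output
  phenotype: synapse_loss
apoptosis:
  role: output
  phenotype: apoptosis
autophagy:
  role: output
  phenotype: autophagy
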