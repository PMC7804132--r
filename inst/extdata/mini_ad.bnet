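# Mini Alzheimer's-pathway fixture (synthetic test double, reduced scale).
# One rule per line; roles live in mini_ad_annotation.yaml.
targets, factors
ROS, ROS
MAPK, ROS
CREB, MAPK
APP, MAPK
Dkk1, Abeta | ROS
WNT_can, !Dkk1
WNT_noncan, Dkk1 | Abeta
BACE1, WNT_noncan
Abeta, APP & (BACE1 | !autophagy)
NMDAR, !Abeta
PTEN, PTEN
PI3K_AKT, NMDAR & !PTEN
GSK3b, !WNT_can & !PI3K_AKT
mTORC1, PI3K_AKT
autophagy, !mTORC1
ptau, GSK3b & !autophagy
apoptosis, (ROS & !PI3K_AKT) | ptau
synapse_loss, Abeta & !CREB
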