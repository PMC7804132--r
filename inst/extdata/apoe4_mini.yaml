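# ApoE e4-allele condition for the mini fixture: a documented
# reconstruction, not the published model's own condition file.
# Canonical WNT signaling is silenced (LRP6 internalization) and the
# autophagy program is constitutively suppressed (TFEB suppression,
# encoded here as locked-on mTORC1). Down-regulated synaptic NMDAR
# signaling emerges downstream through elevated amyloid-beta rather than
# being clamped, which keeps the AKT-mediated rescue axis intact.
name: APOE4
pins: {}
overrides:
  WNT_can: "0"
  mTORC1: "1"
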