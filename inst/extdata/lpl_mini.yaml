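# LPL loss-of-function condition for the mini fixture: a documented
# reconstruction, not the published model's own condition file.
# Cholesterol elevation raises beta-secretase activity (BACE1 locked on)
# and mTORC1 hyperactivity suppresses autophagic clearance.
name: LPL
pins: {}
overrides:
  BACE1: "1"
  mTORC1: "1"
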