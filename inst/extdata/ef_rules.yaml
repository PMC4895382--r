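loop_length: 12
positions:
  X:
    position: 1
    allowed:
    - D
    coordination: side chain
  'Y':
    position: 3
    allowed:
    - D
    - 'N'
    - S
    coordination: side chain
  Z:
    position: 5
    allowed:
    - D
    - 'N'
    - S
    - T
    coordination: side chain
  -Y:
    position: 7
    allowed: ~
    coordination: backbone carbonyl
  -X:
    position: 9
    allowed:
    - S
    - T
    - D
    - 'N'
    - E
    - G
    - Q
    coordination: water-mediated
  -Z:
    position: 12
    allowed:
    - E
    - D
    coordination: bidentate side chain
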