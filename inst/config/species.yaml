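# Species presets for silhouette extraction.
# r_d_mm: physical radius of the diamond structuring element used for
#         tail removal (matched to tail-base size).
# threshold: background-subtraction intensity threshold on the 8-bit scale.
default_threshold: 10
rat:
  r_d_mm: 9
  threshold: 10
mouse:
  r_d_mm: 5
  threshold: 10
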