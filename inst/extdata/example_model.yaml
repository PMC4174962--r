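# Example stimulation configuration: cylindrical stack of subject 1 with a
# 9 cm^2 electrode pair at the anterior site and a 12 um fiber 5 mm below
# the fat-muscle boundary.
representation: CM
subject: 1
axial_length_cm: 40
electrodes:
  site: anterior
  area_cm2: 9.0
  gap_cm: 4.0
fiber:
  site: anterior
  depth_mm: 5.0
  diameter_um: 12.0
  length_mm: 63.0
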