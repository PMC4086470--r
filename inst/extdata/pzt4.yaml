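# PZT-4 ceramic constants (stress-charge form, poling along the 3-axis).
# Stiffness in GPa, piezoelectric stress constants in C/m^2, permittivities
# relative clamped (constant-strain) values; density in kg/m^3.
pzt4:
  c11_gpa: 139
  c12_gpa: 77.8
  c13_gpa: 74.3
  c33_gpa: 115
  c44_gpa: 25.6
  c66_gpa: 30.6
  e15: 12.7
  e31: -5.2
  e33: 15.1
  eps11_rel: 370
  eps33_rel: 635
  density: 7500
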