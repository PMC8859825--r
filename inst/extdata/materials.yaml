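water:
  class: dielectric
  frequency: 3.0e+15
  dielectric: 78.4
  refractive_index: 1.333
amino_acid:
  class: dielectric
  frequency: 3.0e+15
  dielectric: 4.0
  refractive_index: 1.5
carbohydrate:
  class: dielectric
  frequency: 3.0e+15
  dielectric: 3.5
  refractive_index: 1.49
lipid:
  class: dielectric
  frequency: 3.0e+15
  dielectric: 2.0
  refractive_index: 1.44
polystyrene:
  class: dielectric
  frequency: 3.0e+15
  dielectric: 2.55
  refractive_index: 1.557
silver:
  class: conducting
  frequency: 2.18e+15
gold:
  class: conducting
  frequency: 2.08e+15
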