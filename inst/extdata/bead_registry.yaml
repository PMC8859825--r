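ALA:
  charge: 0.0
  radius: 0.26
  material_id: amino_acid
ARG:
  charge: 1.0
  radius: 0.35
  material_id: amino_acid
ASN:
  charge: 0.0
  radius: 0.3
  material_id: amino_acid
ASP:
  charge: -1.0
  radius: 0.29
  material_id: amino_acid
ASPP:
  charge: 0.0
  radius: 0.29
  material_id: amino_acid
CYS:
  charge: 0.0
  radius: 0.28
  material_id: amino_acid
GLN:
  charge: 0.0
  radius: 0.31
  material_id: amino_acid
GLU:
  charge: -1.0
  radius: 0.31
  material_id: amino_acid
GLUP:
  charge: 0.0
  radius: 0.31
  material_id: amino_acid
GLY:
  charge: 0.0
  radius: 0.23
  material_id: amino_acid
  pmf_name: ALA
HSD:
  charge: 0.0
  radius: 0.33
  material_id: amino_acid
HSE:
  charge: 0.0
  radius: 0.33
  material_id: amino_acid
HSP:
  charge: 1.0
  radius: 0.33
  material_id: amino_acid
ILE:
  charge: 0.0
  radius: 0.31
  material_id: amino_acid
LEU:
  charge: 0.0
  radius: 0.31
  material_id: amino_acid
LYS:
  charge: 1.0
  radius: 0.34
  material_id: amino_acid
MET:
  charge: 0.0
  radius: 0.32
  material_id: amino_acid
PHE:
  charge: 0.0
  radius: 0.34
  material_id: amino_acid
PRO:
  charge: 0.0
  radius: 0.29
  material_id: amino_acid
SER:
  charge: 0.0
  radius: 0.26
  material_id: amino_acid
THR:
  charge: 0.0
  radius: 0.28
  material_id: amino_acid
TRP:
  charge: 0.0
  radius: 0.37
  material_id: amino_acid
TYR:
  charge: 0.0
  radius: 0.35
  material_id: amino_acid
VAL:
  charge: 0.0
  radius: 0.29
  material_id: amino_acid
BGALNA:
  charge: 0.0
  radius: 0.38
  material_id: carbohydrate
BGLCNA:
  charge: 0.0
  radius: 0.38
  material_id: carbohydrate
AMAN:
  charge: 0.0
  radius: 0.36
  material_id: carbohydrate
BMAN:
  charge: 0.0
  radius: 0.36
  material_id: carbohydrate
AFUC:
  charge: 0.0
  radius: 0.34
  material_id: carbohydrate
BGLC:
  charge: 0.0
  radius: 0.36
  material_id: carbohydrate
AGAL:
  charge: 0.0
  radius: 0.36
  material_id: carbohydrate
DMP:
  charge: -1.0
  radius: 0.33
  material_id: lipid
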