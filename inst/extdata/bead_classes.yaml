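# Residue -> hydropathy class and bead radius (nm) for coarse-grained models.
# Covers the 20 standard residues (three-letter and one-letter codes) plus the
# non-natural residues ADA (2-aminodecanoic acid, long-alkyl hydrophobic,
# modelled like ILE/LEU) and ABZ (aminobenzoyl cap, modelled like PHE),
# and the DPC detergent residue. Unknown residues fall back to `default`.
default:
  class: other
  radius_nm: 0.26
residues:
  ALA: {class: hydrophobic}
  VAL: {class: hydrophobic}
  LEU: {class: hydrophobic}
  ILE: {class: hydrophobic}
  MET: {class: hydrophobic}
  PHE: {class: hydrophobic}
  TRP: {class: hydrophobic}
  PRO: {class: hydrophobic}
  CYS: {class: hydrophobic}
  GLY: {class: polar}
  SER: {class: polar}
  THR: {class: polar}
  ASN: {class: polar}
  GLN: {class: polar}
  TYR: {class: polar}
  HIS: {class: polar}
  LYS: {class: charged_pos}
  ARG: {class: charged_pos}
  ASP: {class: charged_neg}
  GLU: {class: charged_neg}
  ADA: {class: hydrophobic}
  ABZ: {class: hydrophobic}
  DPC: {class: hydrophobic}
  "A": {class: hydrophobic}
  "V": {class: hydrophobic}
  "L": {class: hydrophobic}
  "I": {class: hydrophobic}
  "M": {class: hydrophobic}
  "F": {class: hydrophobic}
  "W": {class: hydrophobic}
  "P": {class: hydrophobic}
  "C": {class: hydrophobic}
  "G": {class: polar}
  "S": {class: polar}
  "T": {class: polar}
  "N": {class: polar}
  "Q": {class: polar}
  "Y": {class: polar}
  "H": {class: polar}
  "K": {class: charged_pos}
  "R": {class: charged_pos}
  "D": {class: charged_neg}
  "E": {class: charged_neg}
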