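# Binding motifs for the BALB/c H-2 class I alleles, as per-position
# log-odds weight tables. Positions are P1..Pn from the N terminus; POmega
# is the C-terminal residue whatever the peptide length. Residues not listed
# at a position carry weight 0 (background). Residue keys are quoted because
# bare Y/N parse as booleans in YAML 1.1. Edit freely: the package reads
# this file at run time, no code change needed.
Kd:
  lengths: [8, 11]
  floor: 0
  anchors: [P2, POmega]
  weights:
    P2: {"Y": 3.0, "F": 2.5}
    POmega: {"L": 2.0, "I": 2.0, "V": 2.0}
Dd:
  lengths: [8, 11]
  floor: 0
  anchors: [P2, P3, POmega]
  weights:
    P2: {"G": 2.5}
    P3: {"P": 2.5}
    P5: {"F": 1.0, "R": 1.0, "I": 1.0, "G": 1.0}
    POmega: {"L": 2.0, "I": 2.0, "F": 2.0}
Ld:
  lengths: [8, 11]
  floor: 0
  anchors: [P2, POmega]
  weights:
    P2: {"P": 3.0}
    POmega: {"F": 2.0, "L": 2.0, "M": 2.0}
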