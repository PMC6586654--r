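# Domain partition rules for an intact human IgG1 crystal structure
# (two heavy chains H/K, two light chains L/M, e.g. PDB entry 1HZH).
# Format: label chain first_residue last_residue
# Residue boundaries are conventional and user-editable: the Fab portion of
# each heavy chain runs to ~residue 230, the hinge to ~237, CH2 is ~238-340
# and CH3 is ~341-443.
Fab1 H 1 230
Fab1 L 1 250
Fab2 K 1 230
Fab2 M 1 250
hinge H 231 237
hinge K 231 237
HalfFcA_CH2 H 238 340
HalfFcA_CH3 H 341 443
HalfFcB_CH2 K 238 340
HalfFcB_CH3 K 341 443
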