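AutoDock 4.2 docking log (synthetic example ligand)
________________________________________________________________

Ligand: example_ligand  (synthetic fixture for parser validation)
Number of runs: 3

DOCKED: MODEL        1
DOCKED: USER    Run = 1
DOCKED: USER    Estimated Free Energy of Binding    =   -7.10 kcal/mol  [=(1)+(2)+(3)-(4)]
DOCKED: USER
DOCKED: ATOM      1  C1  LIG A   1       0.000   0.000   0.000  0.00  0.00    +0.000 C
DOCKED: ATOM      2  N1  LIG A   1       1.400   0.000   0.000  0.00  0.00    +0.000 N
DOCKED: ATOM      3  S1  LIG A   1       2.100   1.200   0.000  0.00  0.00    +0.000 S
DOCKED: ATOM      4  H1  LIG A   1       0.500   0.900   0.000  0.00  0.00    +0.000 H
DOCKED: TER
DOCKED: ENDMDL
DOCKED: MODEL        2
DOCKED: USER    Run = 2
DOCKED: USER    Estimated Free Energy of Binding    =   -6.90 kcal/mol  [=(1)+(2)+(3)-(4)]
DOCKED: USER
DOCKED: ATOM      1  C1  LIG A   1       0.300   0.300   0.300  0.00  0.00    +0.000 C
DOCKED: ATOM      2  N1  LIG A   1       1.700   0.300   0.300  0.00  0.00    +0.000 N
DOCKED: ATOM      3  S1  LIG A   1       2.400   1.500   0.300  0.00  0.00    +0.000 S
DOCKED: ATOM      4  H1  LIG A   1       0.800   1.200   0.300  0.00  0.00    +0.000 H
DOCKED: TER
DOCKED: ENDMDL
DOCKED: MODEL        3
DOCKED: USER    Run = 3
DOCKED: USER    Estimated Free Energy of Binding    =   -5.00 kcal/mol  [=(1)+(2)+(3)-(4)]
DOCKED: USER
DOCKED: ATOM      1  C1  LIG A   1       5.000   5.000   5.000  0.00  0.00    +0.000 C
DOCKED: ATOM      2  N1  LIG A   1       6.400   5.000   5.000  0.00  0.00    +0.000 N
DOCKED: ATOM      3  S1  LIG A   1       7.100   6.200   5.000  0.00  0.00    +0.000 S
DOCKED: ATOM      4  H1  LIG A   1       5.500   5.900   5.000  0.00  0.00    +0.000 H
DOCKED: TER
DOCKED: ENDMDL

Run completed.
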