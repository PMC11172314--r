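# Component registry: phase-forming species, water and model proteins.
# Molar masses (g/mol) computed from standard atomic weights.
components:
  - name: "[C2C1Im][C4F9SO3]"
    molar_mass_g_mol: 410.26
    role: fluorinated_IL
  - name: "[N1112(OH)][C4F9SO3]"
    molar_mass_g_mol: 403.26
    role: fluorinated_IL
  - name: "[C2C1Py][C4F9SO3]"
    molar_mass_g_mol: 407.25
    role: fluorinated_IL
  - name: "[C4C1Im][CF3SO3]"
    molar_mass_g_mol: 288.29
    role: fluoro_containing_IL
  - name: "[C2C1Im][CF3SO3]"
    molar_mass_g_mol: 260.23
    role: fluoro_containing_IL
  - name: "[N1112(OH)][CF3SO3]"
    molar_mass_g_mol: 253.24
    role: fluoro_containing_IL
  - name: "[C2C1Im]Cl"
    molar_mass_g_mol: 146.62
    role: conventional_IL
  - name: "[N1112(OH)]Cl"
    molar_mass_g_mol: 139.62
    role: conventional_IL
  - name: "K3PO4"
    molar_mass_g_mol: 212.27
    role: inorganic_salt
  - name: "glucose"
    molar_mass_g_mol: 180.16
    role: carbohydrate
  - name: "sucrose"
    molar_mass_g_mol: 342.30
    role: carbohydrate
  - name: "[N1112(OH)][H2PO4]"
    molar_mass_g_mol: 201.16
    role: stabilizer
  - name: "water"
    molar_mass_g_mol: 18.015
    role: water
  - name: "lysozyme"
    molar_mass_g_mol: 14300.0
    role: protein
  - name: "BSA"
    molar_mass_g_mol: 66500.0
    role: protein
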