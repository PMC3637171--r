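{
  "species": [
    {"name": "mRNA_A", "initial_count": 0},
    {"name": "protein_A", "initial_count": 0},
    {"name": "dimer_A", "initial_count": 0},
    {"name": "mRNA_B", "initial_count": 0},
    {"name": "protein_B", "initial_count": 0},
    {"name": "dimer_B", "initial_count": 0}
  ],
  "reactions": [
    {"name": "translation_A",
     "reactants": {"mRNA_A": 1}, "products": {"mRNA_A": 1, "protein_A": 1},
     "rate": 1, "rate_units": "per-mRNA-per-second"},
    {"name": "mrna_A_degradation",
     "reactants": {"mRNA_A": 1}, "rate": 2, "rate_units": "per-second"},
    {"name": "protein_A_decay",
     "reactants": {"protein_A": 1}, "rate": 0.01,
     "rate_units": "per-second"},
    {"name": "dimerization_A",
     "reactants": {"protein_A": 2}, "products": {"dimer_A": 1},
     "rate": 1, "rate_units": "uM-per-second",
     "volume_class": "inverse-volume"},
    {"name": "dimer_A_dissociation",
     "reactants": {"dimer_A": 1}, "products": {"protein_A": 2},
     "rate": 1, "rate_units": "per-second"},
    {"name": "translation_B",
     "reactants": {"mRNA_B": 1}, "products": {"mRNA_B": 1, "protein_B": 1},
     "rate": 1, "rate_units": "per-mRNA-per-second"},
    {"name": "mrna_B_degradation",
     "reactants": {"mRNA_B": 1}, "rate": 2, "rate_units": "per-second"},
    {"name": "protein_B_decay",
     "reactants": {"protein_B": 1}, "rate": 0.01,
     "rate_units": "per-second"},
    {"name": "dimerization_B",
     "reactants": {"protein_B": 2}, "products": {"dimer_B": 1},
     "rate": 1, "rate_units": "uM-per-second",
     "volume_class": "inverse-volume"},
    {"name": "dimer_B_dissociation",
     "reactants": {"dimer_B": 1}, "products": {"protein_B": 2},
     "rate": 1, "rate_units": "per-second"}
  ],
  "genes": [
    {"name": "gene_A", "position": 0.5, "rate": 1,
     "rate_units": "per-gene-per-second", "mrna": "mRNA_A",
     "sites": [{"tf": "dimer_B", "kon": 100, "koff": 0.1, "factor": 0.1}]},
    {"name": "gene_B", "position": 0.5, "rate": 1,
     "rate_units": "per-gene-per-second", "mrna": "mRNA_B",
     "sites": [{"tf": "dimer_A", "kon": 100, "koff": 0.1, "factor": 0.1}]}
  ],
  "config": {
    "T": 50, "C": 40, "D": 20, "V_birth": 1.1e-15,
    "t_end": 15000, "grid_dt": 5, "seed": 1, "max_cells": 64
  }
}
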