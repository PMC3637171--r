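{
  "species": [
    {"name": "mRNA", "initial_count": 0},
    {"name": "protein", "initial_count": 0},
    {"name": "dimer", "initial_count": 0}
  ],
  "reactions": [
    {"name": "translation",
     "reactants": {"mRNA": 1}, "products": {"mRNA": 1, "protein": 1},
     "rate": 1, "rate_units": "per-mRNA-per-second", "delay": 1000},
    {"name": "mrna_degradation",
     "reactants": {"mRNA": 1}, "rate": 2, "rate_units": "per-second"},
    {"name": "protein_decay",
     "reactants": {"protein": 1}, "rate": 0.01, "rate_units": "per-second"},
    {"name": "dimerization",
     "reactants": {"protein": 2}, "products": {"dimer": 1},
     "rate": 1, "rate_units": "uM-per-second",
     "volume_class": "inverse-volume"},
    {"name": "dimer_dissociation",
     "reactants": {"dimer": 1}, "products": {"protein": 2},
     "rate": 1, "rate_units": "per-second"}
  ],
  "genes": [
    {"name": "gene_a", "position": 0.05, "rate": 1,
     "rate_units": "per-gene-per-second", "mrna": "mRNA",
     "initial_copies": 2,
     "sites": [{"tf": "dimer", "kon": 100, "koff": 0.1, "factor": 0.1}]}
  ],
  "config": {
    "T": 200, "C": 40, "D": 20, "V_birth": 1.1e-15,
    "t_end": 24000, "grid_dt": 5, "seed": 1, "max_cells": 64
  }
}
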