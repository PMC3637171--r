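{
  "species": [
    {"name": "M1", "initial_count": 50},
    {"name": "M2", "initial_count": 50},
    {"name": "M3", "initial_count": 50},
    {"name": "mRNA_a", "initial_count": 10},
    {"name": "enz_a", "initial_count": 100},
    {"name": "mRNA_b", "initial_count": 10},
    {"name": "enz_b", "initial_count": 100}
  ],
  "reactions": [
    {"name": "influx_M1", "products": {"M1": 1},
     "rate": 100, "rate_units": "uM-per-second",
     "volume_class": "proportional-volume"},
    {"name": "conv_M1_M2", "rate_law": "michaelis_menten",
     "reactants": {"M1": 1}, "products": {"M2": 1},
     "enzyme": "enz_a", "substrate": "M1", "rate": 10, "Km": 1},
    {"name": "conv_M2_M3", "rate_law": "michaelis_menten",
     "reactants": {"M2": 1}, "products": {"M3": 1},
     "enzyme": "enz_b", "substrate": "M2", "rate": 10, "Km": 1},
    {"name": "use_M1", "reactants": {"M1": 1},
     "rate": 1, "rate_units": "per-second"},
    {"name": "use_M3", "reactants": {"M3": 1},
     "rate": 1, "rate_units": "per-second"},
    {"name": "mrna_a_degradation", "reactants": {"mRNA_a": 1},
     "rate": 1, "rate_units": "per-second"},
    {"name": "mrna_b_degradation", "reactants": {"mRNA_b": 1},
     "rate": 1, "rate_units": "per-second"},
    {"name": "translation_a",
     "reactants": {"mRNA_a": 1}, "products": {"mRNA_a": 1, "enz_a": 1},
     "rate": 1, "rate_units": "per-mRNA-per-second"},
    {"name": "translation_b",
     "reactants": {"mRNA_b": 1}, "products": {"mRNA_b": 1, "enz_b": 1},
     "rate": 1, "rate_units": "per-mRNA-per-second"},
    {"name": "enz_a_decay", "reactants": {"enz_a": 1},
     "rate": 0.01, "rate_units": "per-second"},
    {"name": "enz_b_decay", "reactants": {"enz_b": 1},
     "rate": 0.01, "rate_units": "per-second"}
  ],
  "genes": [
    {"name": "gene_a", "position": 0.5, "rate": 1,
     "rate_units": "per-gene-per-second", "mrna": "mRNA_a"},
    {"name": "gene_b", "position": 0.5, "rate": 1,
     "rate_units": "per-gene-per-second", "mrna": "mRNA_b"}
  ],
  "config": {
    "T": 50, "C": 40, "D": 20, "V_birth": 1.6605390671738466e-17,
    "t_end": 18000, "grid_dt": 5, "seed": 1, "max_cells": 64
  }
}
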