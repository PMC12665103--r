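{
  "compartments": [
    { "id": "POC", "volume_uL": 300, "role": "organoid-chamber" },
    { "id": "LOC", "volume_uL": 300, "role": "organoid-chamber" },
    { "id": "CC", "volume_uL": 210, "role": "channel" },
    { "id": "LOOP", "volume_uL": 390, "role": "tubing" }
  ],
  "convective_edges": [
    { "from": "CC", "to": "LOOP" },
    { "from": "LOOP", "to": "CC" }
  ],
  "membrane_interfaces": [
    {
      "from": "POC", "to": "CC",
      "pore_um": 1.0, "porosity": 0.8, "kappa_m2": 2.5e-14,
      "thickness_um": 50, "area_cm2": 0.2, "tortuosity": 1.0
    },
    {
      "from": "LOC", "to": "CC",
      "pore_um": 1.0, "porosity": 0.8, "kappa_m2": 2.5e-14,
      "thickness_um": 50, "area_cm2": 0.2, "tortuosity": 1.0
    }
  ],
  "fluid": { "rho_kg_m3": 1030, "mu_Pa_s": 0.0025 },
  "shear_fluid": { "rho_kg_m3": 1000, "mu_Pa_s": 0.001 },
  "flow": { "rate_uL_min": 600, "enabled": true },
  "channel": { "width_cm": 0.7, "height_cm": 0.3, "length_cm": 1.0 },
  "no_flow_path_cm": 0.05,
  "species": [
    { "name": "glucose", "molecular_weight_kDa": 0.18,
      "diffusivity_m2_s": 9.58e-10, "default_units": "mM" },
    { "name": "dextran4", "molecular_weight_kDa": 4.0,
      "diffusivity_m2_s": 1.35e-10, "default_units": "ug/mL" },
    { "name": "dextran70", "molecular_weight_kDa": 70.0,
      "diffusivity_m2_s": 2.3e-11, "default_units": "ug/mL" }
  ],
  "surrogates": { "insulin": "dextran4", "feta": "dextran70" }
}
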