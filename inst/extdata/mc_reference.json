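{
  "description": "Reference configuration of the counterion-bridging toy model: intermediate ion load maximises cluster size (bridging), high load disperses clusters (overcharging).",
  "ion_counts": [2, 30, 120],
  "seeds": [1, 2, 3, 4],
  "params": {
    "n_particles": 12,
    "sites_per_particle": 4,
    "box_nm": [22, 22],
    "ion_count": 30,
    "bind_energy_kT": -4,
    "second_bind_energy_kT": -2,
    "bridge_energy_kT": -2,
    "charge_penalty_kT": 0.08,
    "contact_radius_nm": 1.5,
    "max_sites_per_ion": 2,
    "move_sizes": {"particle": 1.0, "ion": 2.0},
    "n_sweeps": 40000,
    "sample_every": 100,
    "seed": 1
  }
}
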