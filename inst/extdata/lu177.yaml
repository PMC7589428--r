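# Lutetium-177 constants for organ-level dosimetry.
# half_life_h: physical half-life in hours.
# local_energy_per_decay_J: mean locally-absorbed (non-penetrating) energy per
#   nuclear transformation, in joules. This value is NOT universal: review it
#   against your preferred decay-data compilation before clinical use.
#   2.3697e-14 J corresponds to ~147.9 keV mean electron energy per decay.
name: Lu-177
half_life_h: 159.53
local_energy_per_decay_J: 2.3697e-14
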