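label,porosity,dissolved_sulfide_um,avs_umol_per_g,solid_grain_density_g_cm3,bulk_volume_cm3
littoral-avs-low,0.9,30,0.3,1.67,1
littoral-avs-high,0.9,30,0.6,1.67,1
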