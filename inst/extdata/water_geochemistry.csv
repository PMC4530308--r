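label,temperature_c,ph,conductivity_ms_cm,bicarbonate_mM,calcium_mM,sulfide_uM
basin-jun2012,29.6,7.03,28.9,2,11.1,33.1
basin-oct2013,31.7,7.32,32.6,2,11.1,0
outflow-a-oct2013,30.0,7.10,29.5,2,,0
outflow-b-oct2013,29.0,7.11,29.7,2,,0
outflow-c-oct2013,27.3,7.19,27.5,2,,0
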