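"muscle","a0","a1","a2"
"patellar_tendon",0.045,-0.00015,0
"hamstrings_hip",0.06,0,0
"hamstrings_knee",0.03,0,0
"gastrocnemius_knee",0.02,0,0
"achilles",0.05,0,0
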