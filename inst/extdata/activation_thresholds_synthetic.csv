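# Synthetic platelet-activation threshold configuration (NOT literature data).
# Shaped like published shear--exposure activation loci (approximately
# constant stress-time product); replace with transcribed experimental points
# via activation_curve(points = ...) for real assessments.
exposure_s,wss_pa,citation_tag
0.003,420,synthetic-config
0.01,250,synthetic-config
0.03,150,synthetic-config
0.1,90,synthetic-config
0.3,55,synthetic-config
1,32,synthetic-config
3,20,synthetic-config
10,12,synthetic-config
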