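# Fibrillation time-course parameters per solvent condition.
# Logistic bound-fraction trajectory f(t) = plateau_frac/(1 + exp(-rate_per_min*(t - t_half_min))),
# lag (tangent convention) = t_half_min - 2/rate_per_min.
# Encoded qualitative orderings: NaCl shortens the lag and accelerates nucleation;
# trehalose without salt blocks lysozyme fibrillation (plateau ~ 0) and for insulin
# extends the lag from 80 to ~240 min while lowering the final measured ratio by
# ~10% (plateau_frac 0.864 maps to a 10% lower ratio plateau than 0.90);
# with salt present trehalose loses most of its effect. t_max_min is the span of
# the corresponding kinetic experiment.
protein,trehalose_mM,nacl_mM,t_half_min,rate_per_min,plateau_frac,t_max_min
lysozyme,0,0,150,0.025,0.90,240
lysozyme,150,0,150,0.025,0.01,240
lysozyme,300,0,150,0.025,0.01,240
lysozyme,0,25,55,0.050,0.90,240
lysozyme,150,25,70,0.035,0.80,240
lysozyme,300,25,80,0.030,0.80,240
lysozyme,0,50,45,0.060,0.90,240
lysozyme,150,50,55,0.050,0.90,240
lysozyme,300,50,60,0.050,0.90,240
insulin,0,0,130,0.040,0.90,420
insulin,300,0,290,0.040,0.864,420
insulin,0,100,45,0.080,0.90,420
insulin,300,100,50,0.080,0.90,420
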