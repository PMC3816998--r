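# provenance: Zatsiorsky-Seluyanov adult male mass regressions (body mass kg, stature m);
# CoM fractions and radii of gyration (fractions of segment length, proximal origin,
# axes x=flexion y=abduction z=longitudinal) from de Leva's 1996 adjustment of the
# same dataset. Hand length is measured wrist centre -> 3rd metacarpal head.
segment,quantity,b0,b_mass,b_stature
upper_arm,mass,0.25,0.03012,-0.27
upper_arm,com_fraction,0.5772,0,0
upper_arm,rgyr_x,0.285,0,0
upper_arm,rgyr_y,0.269,0,0
upper_arm,rgyr_z,0.158,0,0
forearm,mass,0.3185,0.01445,-0.114
forearm,com_fraction,0.4574,0,0
forearm,rgyr_x,0.276,0,0
forearm,rgyr_y,0.265,0,0
forearm,rgyr_z,0.121,0,0
hand,mass,-0.1165,0.0036,0.175
hand,com_fraction,0.79,0,0
hand,rgyr_x,0.628,0,0
hand,rgyr_y,0.513,0,0
hand,rgyr_z,0.401,0,0
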