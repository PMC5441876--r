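# Founder strain, rich medium (LB / serine chemotaxis), 0.3% w/v agar.
# Transport coefficients are the agar-corrected values derived from the
# founder's swimming statistics (run speed 18.7 um/s, tumble frequency
# 1.45 /s) at C = 0.3%.
Db: 0.02        # cm^2/h
Dc: 0.036       # cm^2/h
k0: 0.65        # cm^2/h
KD: 2.0         # mM
kg: 1.23        # 1/h
Kg: 0.13        # mM
"Y": 5.0e+7       # cells/mL/mM
c0: 1.0         # mM
C: 0.3          # % w/v
inoculum_cells: 1.0e+6
inoculum_radius: 0.25   # cm
depth: 0.4              # cm
domain_radius: 7.5      # cm
medium: rich
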