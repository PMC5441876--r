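# Founder strain, minimal medium (M63 / 0.18 mM galactose), 0.3% w/v
# agar. Transport from founder swimming statistics (run speed 20.7
# um/s, tumble frequency 2 /s) at C = 0.3%. Kg for galactose is taken
# sub-saturating relative to c0 (see the methods vignette).
Db: 0.021       # cm^2/h
Dc: 0.036       # cm^2/h
k0: 0.66        # cm^2/h
KD: 0.1         # mM
kg: 0.125       # 1/h
Kg: 1.0e-3      # mM
"Y": 3.0e+8       # cells/mL/mM
c0: 0.18        # mM
C: 0.3          # % w/v
inoculum_cells: 1.0e+6
inoculum_radius: 0.25   # cm
depth: 0.4              # cm
domain_radius: 7.5      # cm
medium: minimal
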