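# Baseline parameter set of the coupled-myosin model (version 1).
#
# These values are a RECONSTRUCTION: they were calibrated once (see
# scripts/calibrate_baseline.R) so that the simulated baseline condition
# shows a sub-um/s sliding-velocity plateau, a motile fraction that rises
# steeply with filament length and approaches 1 for long filaments, and
# run/stop structure resolvable at the 1/3 s analysis time resolution.
# They are not measured single-molecule constants.
version: 1
k_attach: 25        # 1/s per free binding site
k_stroke: 900       # 1/s, unstrained main power-stroke rate
k_detach: 120       # 1/s, unstrained secondary-step (pre-detachment) rate
c_coupling: 1.3     # dimensionless impact of mechanical coupling
d_main: 8           # nm, main power-stroke distance
d_second: 4         # nm, secondary step distance
kappa: 1.4          # pN/nm, crossbridge stiffness
site_spacing: 0.0355 # um, actin helix repeat
kT: 4.19            # pN nm, thermal energy at 30 C
noise_sigma: 0.02   # um, measurement noise added at sampling
bind_sigma: 3.5     # nm, binding-offset spread (thermal + site registration)
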