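# Default experiment configuration: 4.5 um superparamagnetic beads in
# water, nebulized at a 3.5 um mass median diameter, driven by a 3.4 mT /
# 40 Hz rotating field cambered to roll wheels in +x.
field.flux_density_mT: 3.4
field.frequency_Hz: 40
field.axis: [0.0, 0.86602540378, -0.5]
bead.diameter_um: 4.5
bead.density_g_cm3: 1.5
bead.chi_imag: 0.1
fluid.viscosity_mPa_s: 1.0
model.coupling_length_um: 0.05
aerosol.mmd_um: 3.5
aerosol.gsd: 2.0
aerosol.concentration_per_ml: 4.0e+6
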