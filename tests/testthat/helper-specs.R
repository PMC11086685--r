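# Shared fixtures: the bench conditions used throughout the tests.
default_bead <- bead_spec()                      # 4.5 um, 1.5 g/cm3, chi'' 0.1
default_field <- field_spec(3.4, 40)             # 3.4 mT, 40 Hz, +x rolling
default_fluid <- fluid_spec(1)                   # water
default_H <- field_H_from_B(default_field$flux_density)
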