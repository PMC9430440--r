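# Synthetic O-D stretch potential map (representative, not transcribed from
# any published parameter table). Form: omega = omega0 + sum_s c_s * phi_s,
# with phi_s the electrostatic potential (atomic units, e/Bohr) at the HDO
# probe's D, O and H sites from all atoms of other molecules within the
# cutoff. Signs follow the physical convention: a short, strong H-bond to
# the D atom lowers phi_D and red-shifts the stretch.
parameter,value
omega0_cm1,2650
coeff_D_cm1_per_au,2300
coeff_O_cm1_per_au,-2000
coeff_H_cm1_per_au,-300
cutoff_angstrom,7.8
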