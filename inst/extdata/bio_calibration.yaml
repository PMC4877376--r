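# Calibration of the conductance-based dopaminergic-neuron model.
#
# This is a synthetic calibration produced for this package: the values
# below were fitted (see the methods vignette) so that the model shows
# the canonical behaviours of the cell type -- 1-4 Hz pacemaking in
# isolation, pacemaking sustained by the ERG current when the SK
# conductance is removed, NMDA-driven firing up to about 50 Hz over
# gbar_nmda in [0, 12] mS/cm2, depolarization block under AMPA alone at
# low conductance, and a > 40 % frequency gain under co-activation.
# Treat this file as the single source of truth for the default
# biophysical parameter set; bio_params() reads it.
#
# Units: potentials mV, conductances mS/cm2, capacitance uF/cm2,
# calcium uM, magnesium mM, radius cm, pump rate cm/ms, time ms.
version: 1
cm: 1.0            # membrane capacitance
gbar_ca: 1.0       # L-type Ca maximal conductance
e_ca: 100.0        # Ca reversal
gbar_kca: 9.0      # SK maximal conductance
k_ca: 0.7          # SK half-activation [Ca]
gbar_erg: 2.0      # ERG maximal conductance
gbar_k: 1.0        # instantaneous K conductance (half -10 mV, slope 7 mV)
e_k: -90.0         # K reversal (shared by SK, ERG and g_K)
g_l: 0.05          # leak conductance (limits input resistance)
e_l: -50.0         # leak reversal (leak has its own reversal, not e_k)
gbar_ampa: 0.0     # AMPAR conductance density (control parameter)
e_ampa: 0.0        # AMPA reversal
gbar_nmda: 0.0     # NMDAR conductance density (control parameter)
e_nmda: 0.0        # NMDA reversal
mg: 1.5            # magnesium concentration in the NMDA block factor
radius: 2.0e-4     # cell radius (2 um), enters as surface-to-volume 2/r
beta_buf: 0.05     # ratio of free to total intracellular calcium
z: 2.0             # calcium valence
faraday: 96485.0   # Faraday constant, C/mol
p_ca: 1.2e-5       # calcium pump rate
erg_vhalf: -47.4   # ERG activation half-voltage
erg_slope: 2.0     # ERG activation slope
erg_tau_base: 62.0 # ERG time-constant baseline, ms
erg_tau_amp: 300.0 # ERG time-constant bump amplitude, ms
erg_tau_v1: -50.4  # first tau sigmoid midpoint
erg_tau_v2: -63.4  # second tau sigmoid midpoint
erg_tau_slope: 2.0 # tau sigmoid slope (decreasing-sigmoid convention)
v_spike: -40.0     # spike-registration threshold, mV
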