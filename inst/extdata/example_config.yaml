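# Example run configuration. Every field is optional; omitted fields
# fall back to the baseline tonically-firing parameter set.
model:
  cm: 0.6                 # uF/cm2
  gbar:                   # mS/cm2, overrides only
    A: 20
  coupling_c: 1.0         # KCa coupling coefficient
  # kca_fixed_ca: 15      # uncouple KCa at a fixed calcium (uM)
  # h_act_v_half: -50     # shift the h activation half-voltage (mV)
calcium:
  tau_ca: 200             # ms
  f: 14.96                # uM per uA/cm2
  ca_base: 0.05           # uM
  ca_out: 3000            # uM
  z: 2
  log_base: ln
stimulus:
  kind: tonic             # zero | tonic | synaptic
  amplitude: 0.5          # uA/cm2 (impulse height for synaptic)
  # lambda: 8             # ms, synaptic mean gap
  # seed: 1
analysis:
  levels: [0, 0.2, 0.4, 0.6, 0.8, 1.0, 1.2, 1.4, 1.6, 1.8, 2.0]
  duration: 12000         # ms per simulation
  transient: 2000         # ms discarded
  percents: [70, 85, 100, 115, 130]
run:
  out_dir: results
  seed: 1
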