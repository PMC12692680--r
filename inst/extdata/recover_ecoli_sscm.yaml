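# Example run configuration: recover the E. coli/SSCM kinetic constants
# from noiseless synthetic observations (see ?read_run_config).
#   segrowth recover --config recover_ecoli_sscm.yaml --out results/
schema_version: 1
seed: 1
scenario:
  preset: ecoli_sscm
  S0: 200        # g/L, raised so the trajectory brackets K_S
  horizon: 48    # h
noise:
  kind: none
  sampling_interval: 1
fit:
  free:
    'ecoli:mu_max': [0.01, 1000]
    'ecoli:K_S': [0.1, 1.0e+5]
    'ecoli:Y_XS': [1.0e-3, 1]
    'ecoli:k_d': [1.0e-8, 0.1]
    'lysis:k_s': [1.0e-4, 10]
  settings:
    pop_size: 40
    generations: 60
output:
  prefix: ecoli_sscm
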