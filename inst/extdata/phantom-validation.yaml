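# Solid-phantom validation run: steady diffusion solve probed at the
# five detector distances. Units carried in key names (cm-based).
scene:
  kind: phantom
  phantom:
    mu_a_per_cm: 0.224
    mu_s_prime_per_cm: 4.99
    diffuser_length_cm: 2
    diffuser_diameter_cm: 0.098
    intensity_mW_per_cm: 100
    block_edge_cm: 10
    detector_distances_mm: [5, 10, 15, 20, 25]
task: validate-phantom
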