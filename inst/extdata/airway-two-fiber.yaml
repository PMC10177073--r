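# Synthetic airway-tumor scene with one vessel and two sequentially
# illuminated fibers; task runs the domination sub-maps optimizer.
scene:
  kind: airway
  airway:
    tumor_semiaxes_cm: [1.5, 1.2, 1.2]
    vessels:
      - point_cm: [2.4, 0, 0]
        dir: [0, 0, 1]
        radius_cm: 0.5
    bronchus:
      point_cm: [0, -3, 0]
      dir: [1, 0, 0]
      radius_cm: 0.6
    margin_cm: 1.2
    target_h_cm: 0.35
fibers:
  - entry_point_cm: [-0.5, 0, -0.75]
    axis: [0, 0, 1]
    diffuser_length_cm: 1.5
  - entry_point_cm: [0.6, 0, -0.75]
    axis: [0, 0, 1]
    diffuser_length_cm: 1.5
limits:
  cs_irradiance_max_mW_cm2: 8.6
  cs_fluence_max_J_cm2: 9.5
task: optimize
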