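# Example scenario file: two pumps into a 7 Fr catheter, pump A stepped
# 10 -> 20 mL/h at t = 0.1 h while pump B delivers critical medication at
# 1 mL/h. Components may be catalog names (strings) or explicit parameter
# maps, as shown for the catheter.
name: case2_from_file
events: "pump A stepped 10 -> 20 mL/h at t = 0.1 h"
venous_pressure_mbar: 0
mixing_point: "Discofix C 3-gang"
catheter:
  name: "Careflow 7Fr"
  french_size: 7
  length_m: 0.16
  inner_diameter_mm: 1.6
branches:
  - drug: drug_A
    syringe: "Omnifix 50mL"
    line: "Standard line 1m"
    schedule:
      duration_h: 0.6
      events:
        - {time_h: 0.0, set_flow_ml_h: 10}
        - {time_h: 0.1, set_flow_ml_h: 20}
  - drug: drug_B
    syringe: "Omnifix 50mL"
    line: "Standard line 1m"
    schedule:
      duration_h: 0.6
      events:
        - {time_h: 0.0, set_flow_ml_h: 1}
grid:
  duration_h: 0.6
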