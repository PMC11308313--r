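# Component catalog for typical multi-infusion setups.
#
# Inner diameters, catheter lengths and syringe compliances are NOT published
# by the manufacturers in a single authoritative place; the values below are
# documented engineering estimates chosen to reproduce the qualitative
# regimes (a 1 Fr neonatal catheter has a resistance orders of magnitude
# above a 7 Fr central line). Every field can be overridden when building a
# scenario.
#
# Units: length_m metres, inner_diameter_mm millimetres,
#        compliance_ml_mbar mL per mbar, dead_volume_ml mL.
syringes:
  "Omnifix 50mL":
    nominal_volume_ml: 50
    compliance_ml_mbar: 0.002   # ~2 uL/mbar, air-filled rubber plunger
  "Rigid 50mL":
    nominal_volume_ml: 50
    compliance_ml_mbar: 0.0     # idealized incompressible reference
tubing:
  "Standard line 1m":
    length_m: 1.0
    inner_diameter_mm: 1.0
mixing_points:
  "Discofix C 3-gang":
    dead_volume_ml: 0.5
catheters:
  "Careflow 7Fr":
    french_size: 7
    length_m: 0.16
    inner_diameter_mm: 1.6      # estimate for a 7 Fr single-lumen CVC
  "Premicath 1Fr":
    french_size: 1
    length_m: 0.30
    inner_diameter_mm: 0.3      # estimate for a 1 Fr neonatal PICC
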