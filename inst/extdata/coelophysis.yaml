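# Segment dimension set for a gracile ~2.6 m theropod (reference mass 21 kg
# at 0.97 kg/L whole-body density). Dimensions in metres; radial dimensions
# are normalised at build time so the closed-form mass matches the requested
# total mass exactly.
taxon: coelophysis
reference_mass: 21
flesh_density: 0.97
mean_height: 0.45
skin_reflectivity_pct: 15
segments:
  - name: head
    shape: ellipsoid
    dimensions: {a: 0.13, b: 0.045, c: 0.040}
  - name: neck
    shape: truncated_cone
    dimensions: {r1: 0.040, r2: 0.030, L: 0.40}
  - name: torso
    shape: elliptical_cylinder
    dimensions: {a: 0.085, b: 0.065, L: 0.65}
  - name: front_legs
    shape: cylinder
    dimensions: {r: 0.015, L: 0.25}
    count: 2
  - name: hind_legs
    shape: cylinder
    dimensions: {r: 0.035, L: 0.55}
    count: 2
  - name: tail
    shape: truncated_cone
    dimensions: {r1: 0.050, r2: 0.008, L: 1.30}
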