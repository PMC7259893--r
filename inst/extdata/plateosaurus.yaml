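# Segment dimension set for a ~6 m prosauropod (reference mass 850 kg at
# 0.97 kg/L whole-body density). Dimensions in metres; radial dimensions are
# normalised at build time so the closed-form mass matches the requested
# total mass exactly.
taxon: plateosaurus
reference_mass: 850
flesh_density: 0.97
mean_height: 1.10
skin_reflectivity_pct: 15
segments:
  - name: head
    shape: ellipsoid
    dimensions: {a: 0.18, b: 0.09, c: 0.08}
  - name: neck
    shape: truncated_cone
    dimensions: {r1: 0.13, r2: 0.10, L: 1.20}
  - name: torso
    shape: elliptical_cylinder
    dimensions: {a: 0.36, b: 0.30, L: 1.90}
  - name: front_legs
    shape: cylinder
    dimensions: {r: 0.07, L: 0.70}
    count: 2
  - name: hind_legs
    shape: cylinder
    dimensions: {r: 0.11, L: 1.00}
    count: 2
  - name: tail
    shape: truncated_cone
    dimensions: {r1: 0.18, r2: 0.01, L: 2.40}
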