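# 100 nm silver nanocube on a glass-air interface, 450 nm, normal-incidence
# illumination from below; linear polarization rotates the image pattern.
modality: iscat
layers:
  - {material: air}
  - {material: glass}
illumination: {wavelength_nm: 450, theta_deg: 0, polarization: TM, direction: up}
optics: {"NA": 1.42, "n": 1.5, n_prime: 1.0, mag: 160}
image: {fov_um: 4.4, pixels: 61}
scatterer: {engine: bem, shape: cube, side_nm: 100, divisions: 5,
            material: Ag, position_nm: [0, 0, 51]}
focal_planes_um: [-0.4]
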