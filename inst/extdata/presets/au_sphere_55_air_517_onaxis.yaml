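# Same 55 nm gold sphere in air but near-normal (-2 degree) illumination;
# the focus-correlation map shows the two-ridge crossing ambiguity.
modality: iscat
layers:
  - {material: air}
  - {material: glass}
illumination: {wavelength_nm: 517, theta_deg: -2, polarization: TM, direction: up}
optics: {"NA": 1.3, "n": 1.5, n_prime: 1.0, mag: 133.33}
image: {fov_um: 3.9, pixels: 61}
scatterer: {engine: mie, diameter_nm: 55, material: Au, height_nm: 32.5}
focal_planes_um: [-1, -0.5, 0, 0.5, 1]
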