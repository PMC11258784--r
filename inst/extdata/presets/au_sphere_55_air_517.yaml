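# 55 nm gold sphere in air, 5 nm above a glass substrate; 517 nm, plane
# wave tilted 14 degrees.  Off-axis illumination gives directional fringes
# and an unambiguous focus-correlation maximum.
modality: iscat
layers:
  - {material: air}
  - {material: glass}
illumination: {wavelength_nm: 517, theta_deg: 14, polarization: TM, direction: up}
optics: {"NA": 1.3, "n": 1.5, n_prime: 1.0, mag: 133.33}
image: {fov_um: 3.9, pixels: 61}
scatterer: {engine: mie, diameter_nm: 55, material: Au, height_nm: 32.5}
focal_planes_um: [-1, -0.5, 0, 0.5, 1]
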