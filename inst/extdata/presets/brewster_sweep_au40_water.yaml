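# 40 nm gold sphere at a glass-water interface, TM illumination swept
# around the Brewster angle (~41.6 deg in glass): the reference beam
# vanishes at the Brewster angle and the raw-image Michelson contrast
# peaks there.
modality: iscat
layers:
  - {material: water}
  - {material: glass}
illumination: {wavelength_nm: 520, theta_deg: 40, polarization: TM, direction: up}
optics: {"NA": 1.3, "n": 1.5, n_prime: 1.0, mag: 133.33}
image: {fov_um: 3, pixels: 61}
scatterer: {engine: mie, diameter_nm: 40, material: Au, height_nm: 25}
focal_planes_um: [-0.5, 0, 0.5]
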