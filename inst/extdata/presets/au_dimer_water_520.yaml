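# Coupled 50 nm gold nanospheres (10 nm gap along x) in water, 5 nm above
# glass; TM plane wave at -20 degrees, 520 nm.  BEM engine.
modality: iscat
layers:
  - {material: water}
  - {material: glass}
illumination: {wavelength_nm: 520, theta_deg: -20, polarization: TM, direction: up}
optics: {"NA": 1.3, "n": 1.5, n_prime: 1.0, mag: 133.33}
image: {fov_um: 3, pixels: 61}
scatterer: {engine: bem, shape: dimer, diameter_nm: 50, gap_nm: 10,
            material: Au, height_nm: 30, frequency: 4}
focal_planes_um: [0]
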