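# Silver complex refractive index n + ik versus vacuum wavelength.
# Approximate transcription of the standard published compilation of
# measured silver optical constants (Johnson & Christy); same precision
# caveat as the gold table.
wavelength_nm,n,k
350,0.21,1.42
400,0.05,2.10
450,0.04,2.66
500,0.05,3.13
550,0.06,3.59
600,0.06,4.00
650,0.07,4.40
700,0.08,4.80
800,0.09,5.60
900,0.12,6.40
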