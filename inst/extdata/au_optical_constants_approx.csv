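# Gold complex refractive index n + ik versus vacuum wavelength.
# Approximate transcription of the standard published compilation of
# measured gold optical constants (Johnson & Christy); values accurate to
# about the second decimal in n and k, adequate for the ~few-percent
# tolerances of metal-dependent quantities in this package.
wavelength_nm,n,k
350,1.70,1.95
400,1.66,1.96
450,1.40,1.88
471,1.04,1.83
496,0.92,1.84
521,0.62,2.08
549,0.43,2.46
582,0.31,2.88
617,0.21,3.27
660,0.16,3.75
705,0.13,4.10
756,0.14,4.54
821,0.16,5.13
892,0.17,5.66
1000,0.25,6.70
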