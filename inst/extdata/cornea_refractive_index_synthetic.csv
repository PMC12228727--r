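wavelength_nm,n
200,1.436
210,1.432
220,1.428
230,1.424
240,1.421
250,1.417
260,1.415
270,1.413
280,1.411
290,1.409
300,1.407
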