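wavelength_nm,absorbance,path_mm
200,28.2714,10
205,28.0863,10
210,27.7553,10
215,27.1721,10
220,26.1712,10
225,24.5282,10
230,22.0187,10
235,18.5784,10
240,14.5,10
245,10.4216,10
250,6.9813,10
255,4.4718,10
260,2.8288,10
265,1.8279,10
270,1.2447,10
275,0.9137,10
280,0.7286,10
285,0.6259,10
290,0.5692,10
295,0.538,10
300,0.5209,10
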