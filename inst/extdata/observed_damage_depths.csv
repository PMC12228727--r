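model,source,wavelength_nm,observed_um,sem_um
rhce,far_uvc_222nm,222,27,4
human,far_uvc_233nm,233,53,8
human,uvb_broadband,300,166,25
porcine,far_uvc_233nm,233,28,5
porcine,uvc_254nm,254,71,2
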