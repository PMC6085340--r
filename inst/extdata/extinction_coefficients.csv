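species,wavelength_nm,epsilon
HbO,780,0.0736
HbO,805,0.083
HbO,830,0.0974
HbR,780,0.1105
HbR,805,0.082
HbR,830,0.0693
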