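9e12845a42caeeac506a49db02f2df3e  photon_coefficients.csv
1bb1e9cd517a9265921b7f1156256e04  proton_stopping.csv
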