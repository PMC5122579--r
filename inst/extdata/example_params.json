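{"n":7,"tau_D":0.25,"tau_F":0.2,"p0":0.6,"p1":0.8,"mu_a":0.25,"sigma_a":0.1,"sigma_b":0.05}
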