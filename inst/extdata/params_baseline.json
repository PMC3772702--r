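{"s_ime1":10,"s_ime2":10,"s2_ime2":3,"d_ime1":1,"d2_ime1":1,"d_pime1":1,"d_ime2":8,"p_rim11":0.01,"u_rim11":0.1,"p_ume6":0.3,"u_ume6":0.01,"p_sok2":0.7,"u_sok2":1,"p_ime1":2,"c_sok2":0.05,"c_ime1":0.01,"c1":0.01,"c2":1.4,"c3":2,"hill_n":5}
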