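pitch_deg,speed_m_s,force_N,force_sd_N
0,0.15,0.0020,0.0004
15,0.15,0.0052,0.0004
30,0.15,0.0081,0.0005
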