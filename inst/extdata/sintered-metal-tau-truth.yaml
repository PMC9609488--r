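case: sintered-metal-tau
type: tortuosity
mean_tau: 1.6
std_tau: 0.45
m_ln: 0.4319392
s_ln: 0.2759145
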