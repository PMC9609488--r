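# synthetic tortuosity fixture: sintered-metal-tau
center,value
1.0433471297583856163,0.5461722640452337796
1.1300413892751568490,0.7618728202785132186
1.2167356487919283037,0.8754904929468478869
1.3034299083086995363,0.9689222846842585612
1.3901241678254709910,0.9971825179875467571
1.4768184273422422237,1.0542797240493002597
1.5635126868590134563,0.9896849050703497852
1.6502069463757846890,0.9395085724706292440
1.7369012058925559217,0.7676402148302051698
1.8235954654093273763,0.6615201550790741347
1.9102897249260988310,0.6130740408448596135
1.9969839844428700637,0.4723496137835760389
2.0836782439596412964,0.4094850131701330831
2.1703725034764125290,0.3143230030672148345
2.2570667629931837617,0.2503049235434334219
2.3437610225099549943,0.2082029433160817455
2.4304552820267262270,0.1689846603645760448
2.5171495415434979037,0.1205385461303624950
2.6038438010602691364,0.1026596230201178711
2.6905380605770403690,0.0755528686271653982
2.7772323200938116017,0.0640180795237810379
2.8639265796105832784,0.0472926353238745240
2.9506208391273545111,0.0328741489446444865
3.0373150986441257437,0.0207626203860912552
3.1240093581608969764,0.0219160992964296565
3.2107036176776682090,0.0098045707378764252
3.2973978771944394417,0.0132650074688916344
3.3840921367112106743,0.0074976129171996191
3.4707863962279823511,0.0051906550965227869
3.5574806557447535837,0.0028836972758460077
3.6441749152615248164,0.0046139156413536123
3.7308691747782960491,0.0011534789103384031
3.8175634342950672817,0.0028836972758460077
3.9042576938118385144,0.0000000000000000000
3.9909519533286097470,0.0017302183655075957
4.0776462128453818679,0.0011534789103384031
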