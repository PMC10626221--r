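specimen	days	karyotype
1	0	47,XX,+8,del(20)(q11.2)[7]/48,idem,+19[8]/46,XX[9]
2	42	47,XX,+8,del(20)(q11.2)[1]/48,idem,+19[9]/55–57,XX,+3,+5,+6,+7,+9,+9,+11,?del(11)(q14q23)x2,+15,+18,+19,+21 [cp3]/46,XX[7]
3	142	47,XX,+8,del(20)(q11.2)[1]/48,idem,+19[3]/46,XX[17]
4	364	47,XX,+8,del(20)(q11.2)[1]/48,sl,+19[6]/94,slx2[1]/46,XX[12]
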