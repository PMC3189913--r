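group,ratio,min,max
tiger,canine_height_cbl,0.166,0.230
jaguar,canine_height_cbl,0.160,0.206
leopard,canine_height_cbl,0.132,0.202
lion,canine_height_cbl,0.141,0.185
P_palaeosinensis,canine_height_cbl,0.200,0.200
P_atrox,canine_height_cbl,0.150,0.186
P_spelaea,canine_height_cbl,0.168,0.186
tiger,nasal_length_cbl,0.333,0.417
jaguar,nasal_length_cbl,0.275,0.346
leopard,nasal_length_cbl,0.296,0.347
lion,nasal_length_cbl,0.287,0.357
P_atrox,nasal_length_cbl,0.258,0.291
P_spelaea,nasal_length_cbl,0.301,0.312
tiger,zygomatic_height_cbl,0.095,0.146
jaguar,zygomatic_height_cbl,0.077,0.117
leopard,zygomatic_height_cbl,0.093,0.127
lion,zygomatic_height_cbl,0.098,0.137
P_palaeosinensis,zygomatic_height_cbl,0.124,0.124
P_atrox,zygomatic_height_cbl,0.099,0.121
P_spelaea,zygomatic_height_cbl,0.114,0.149
tiger,p4_length_cbl,0.104,0.141
jaguar,p4_length_cbl,0.105,0.137
leopard,p4_length_cbl,0.113,0.141
lion,p4_length_cbl,0.111,0.142
P_spelaea,p4_length_cbl,0.102,0.137
P_atrox,p4_length_cbl,0.106,0.125
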