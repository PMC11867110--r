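cell_id	indels
cell3	37:5:CTG:2:2,62:2:GG:3:3
cell4	37:5:CTG:2:2,62:2:GG:3:3
cell5	
cell6	
cell1	
cell2	62:24:T:3:4
cell7	61:6:AT:3:3
cell8	61:6:AT:3:3
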