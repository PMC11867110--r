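{"sequence":"GATCGATCGATCGATCGATCGATCGATCGATCGATCGATCGATCGATCGATCGATCGATCGATCGATCGATCGATCGATCGATCGATCGATC","targets":[[0,23],[23,46],[46,69],[69,92]],"cut_positions":[17,40,63,86],"cut_convention":"absolute"}
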