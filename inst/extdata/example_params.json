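{"clock_rate":0.02,"cut_rates":[1,1,1,1],"double_cut_weight":0.05,"long_trim_left":0.05,"long_trim_right":0.05,"trim_means":{"shortLeft":2,"longLeft":20,"shortRight":2,"longRight":10},"insert_mean":1.5,"max_insert_len":10}
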