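((cell3:4.537921388,cell4:4.537921388):12.75999731,(((cell5:2.426384629,cell6:2.426384629):8.752277431,(cell1:9.189225389,cell2:9.189225389):1.98943667):0.2650598708,(cell7:2.139116511,cell8:2.139116511):9.304605419):5.854196769);
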