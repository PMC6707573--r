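drug,package_size,statutory_price_eur,private_price_eur
D01,20,12,14
D01,50,18,21
D01,100,28,33
D02,20,22,26
D02,50,28,33
D02,100,36,42
D03,20,30,35
D03,50,39,45
D03,100,49,57
D04,20,40,46
D04,50,49,56
D04,100,60,69
D05,20,48,55
D05,50,59,68
D05,100,71,82
D06,20,56,64
D06,50,69,79
D06,100,83,95
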