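condition,level,q1,q2,q3,min,max,dr
blue,high,82.0,85.0,89.0,61,232,171
blue,low,21.0,21.0,21.0,21,142,121
gold,high,68.0,74.0,80.0,34,253,219
gold,low,21.0,21.0,34.0,3,229,226
yellow,high,70.0,76.0,87.0,39,253,214
yellow,low,28.0,34.0,39.0,21,228,207
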