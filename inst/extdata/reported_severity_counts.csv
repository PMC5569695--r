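location,below_45g,from_45_to_80g,above_80g,total
front,43,29,33,105
back,39,31,18,88
side,34,28,12,74
all,116,88,63,267
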