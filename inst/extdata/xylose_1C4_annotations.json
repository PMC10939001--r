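{"hydroxyls":[[1,2,7,17],[2,3,9,18],[3,4,11,19],[4,5,13,20]],"ring_atoms":[[1,2,3,4,5,6]],"ringflip":[{"t1":[1,2,3,4],"t2":[4,5,6,1]}],"glycosidic":[]}
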