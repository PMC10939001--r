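{"hydroxyls":[[2,3,8,16],[3,4,10,17],[4,5,12,18],[20,21,26,34],[21,22,28,35],[37,38,43,51],[38,39,45,52],[53,54,59,69],[54,55,61,70],[55,56,63,71]],"ring_atoms":[[1,2,3,4,5,6],[19,20,21,22,23,24],[36,37,38,39,40,41],[53,54,55,56,57,58]],"ringflip":[{"t1":[1,2,3,4],"t2":[4,5,6,1]},{"t1":[19,20,21,22],"t2":[22,23,24,19]},{"t1":[36,37,38,39],"t2":[39,40,41,36]},{"t1":[53,54,55,56],"t2":[56,57,58,53]}],"glycosidic":[{"phi":[1,2,30,23],"psi":[2,30,23,22]},{"phi":[19,20,47,40],"psi":[20,47,40,39]},{"phi":[36,37,65,57],"psi":[37,65,57,56]}]}
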