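# Suillus (rows) x Pinus (columns) ectomycorrhizal compatibility grid.
# Sa = S. americanus, Sg = S. granulatus, Ss = S. spraguei, Sd = S. decipiens;
# Pm = P. monticola, Ps = P. strobus, Pt = P. taeda.
symbiont	Pm	Ps	Pt
Sa	compatible	compatible	incompatible
Sg	compatible	compatible	incompatible
Ss	compatible	compatible	incompatible
Sd	compatible	compatible	compatible
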