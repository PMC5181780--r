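# Peripheral-moiety gene-set definitions for predict_moieties().
# Format: name : reference gene labels : minimum distinct hits
# (omit the trailing ": min" to default to the majority of the set)
chromoprotein : apoprotein : 1
beta_amino_acid : bam1 bam2 bam3 : 2
amino_sugar : asu1 asu2 asu3 : 2
benzoxazolinate : box1 box2 box3 box4 : 2
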