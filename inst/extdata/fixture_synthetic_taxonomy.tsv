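genome_id	lineage
g0001	d__Bacteria;p__Verrucomicrobiota;c__Clostridia;o__Oscillospirales;f__F1;g__G1;s__G1 sp1
g0002	d__Bacteria;p__Bacteroidota;c__Clostridia;o__Oscillospirales;f__F2;g__G2;s__G2 sp2
g0003	d__Bacteria;p__Firmicutes_A;c__Clostridia;o__Oscillospirales;f__F3;g__G3;s__G3 sp3
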