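cell_type	scaling
B.cells	0.932199
Macrophages.M1	0.768851
Macrophages.M2	1.012361
Monocytes	0.50724
Neutrophils	1.212247
NK.cells	0.764869
T.cells.CD4	1.320566
T.cells.CD8	0.646752
Tregs	1.617279
Dendritic.cells	1.217635
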