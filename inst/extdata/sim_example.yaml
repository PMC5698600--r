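# Example EST-library simulation: 100 genes at base proportion 0.01,
# 10 genes with an 8-fold mammary increase, the rest null; one 34,000-EST
# library per tissue.
n_genes: 100
base_proportions: equal
fold_changes: [8, 8, 8, 8, 8, 8, 8, 8, 8, 8,
               1, 1, 1, 1, 1, 1, 1, 1, 1, 1,
               1, 1, 1, 1, 1, 1, 1, 1, 1, 1,
               1, 1, 1, 1, 1, 1, 1, 1, 1, 1,
               1, 1, 1, 1, 1, 1, 1, 1, 1, 1,
               1, 1, 1, 1, 1, 1, 1, 1, 1, 1,
               1, 1, 1, 1, 1, 1, 1, 1, 1, 1,
               1, 1, 1, 1, 1, 1, 1, 1, 1, 1,
               1, 1, 1, 1, 1, 1, 1, 1, 1, 1,
               1, 1, 1, 1, 1, 1, 1, 1, 1, 1]
library_sizes: [34000, 34000, 34000]
seed: 20170
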