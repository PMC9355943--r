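# bundled synthetic run: small planted-module dataset for end-to-end runs
n_donors = 6
n_cell_types = 1
cells_per_donor = 60
n_genes = 300
n_modules_per_type = 3
module_size = 30
factor_sd = 2
noise_sd = 0.3
seed = 11
# analysis stages
min_genes = 50
n_hvgs = 300
B_net = 5
B_assoc = 499
M_perm = 199
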