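n_donors = 2
n_cell_types = 1
cells_per_donor = 10
n_genes = 120
n_modules_per_type = 2
module_size = 15
factor_sd = 2
noise_sd = 0.3
library_size_mean = 2000
lib_sdlog = 0.3
nb_dispersion = 0.3
donor_shift_sd = 0.3
donor_disp_range = 0.80 1.25
n_bulk_samples = 30
bulk_library_size = 2e+05
bulk_dispersion = 0.05
phenotype_effect_grid = NULL
covariate_effects = 0.1 0.1 0.1
frac_modules_preserved = 0.9
seed = 1
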