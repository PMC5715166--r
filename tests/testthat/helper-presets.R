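# shared fixtures: the reference single gene (mean protein 100, burst
# sizes 2 and 10) and a cheap low-copy gene for simulator cross-checks
ref_gene <- function() gene_params(k_g = 5, gamma_g = 95, k_m = 200,
                                   gamma_m = 10, k_p = 100, gamma_p = 1)

small_gene <- function() gene_params(k_g = 2, gamma_g = 2, k_m = 20,
                                     gamma_m = 2, k_p = 4, gamma_p = 1)

bimodal_gene <- function() gene_params(k_g = 0.1, gamma_g = 0.1, k_m = 10,
                                       gamma_m = 10, k_p = 100, gamma_p = 1)
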