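# Shared fixtures, built in code at test time.

single_deme <- function(Ne = 2500, n = 4, mu = 1e-4) {
  demography(data.frame(label = "A", Ne = Ne, n_samples = n), mu = mu)
}

two_deme_split <- function(T_split, Ne = 1000, n = 4, m = 0, mu = 1e-4) {
  demography(
    data.frame(label = c("P1", "P2"), Ne = Ne, n_samples = n),
    events = data.frame(time = T_split, kind = "split", source = "P2",
                        dest = "P1", value = 0),
    migration0 = matrix(c(0, m, m, 0), 2, 2), mu = mu)
}

# small HWE cohort with an optional planted parent-offspring trio
hwe_cohort <- function(n_ind = 12, n_sites = 2000, seed = 1, po_pair = FALSE) {
  set.seed(seed)
  p <- runif(n_sites, 0.05, 0.95)
  geno <- t(replicate(n_ind, rbinom(n_sites, 2L, p)))
  rownames(geno) <- sprintf("ind%02d", seq_len(n_ind))
  if (po_pair) {
    transmit <- function(g) ifelse(g == 0L, 0L,
                            ifelse(g == 2L, 1L, rbinom(n_sites, 1L, 0.5)))
    geno[3, ] <- transmit(geno[1, ]) + transmit(geno[2, ])
  }
  geno
}

toy_coords <- function(n = 4) {
  data.frame(label = paste0("g", seq_len(n)),
             lat = 26 + seq_len(n) * 0.5, lon = 99 + seq_len(n) * 0.1)
}

# brute-force HWE oracle: enumerate all genotype configurations compatible
# with the allele counts and sum multinomial probabilities directly
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  configs <- expand.grid(i = 0:n, j = 0:n)
  configs$k <- n - configs$i - configs$j
  configs <- configs[configs$k >= 0 & 2 * configs$i + configs$j == nA, ]
  pr <- with(configs, choose(n, i) * choose(n - i, j) * 2^j)
  pr <- pr / sum(pr)
  obs <- pr[configs$i == n_AA & configs$j == n_Aa]
  sum(pr[pr <= obs * (1 + 1e-12)])
}
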