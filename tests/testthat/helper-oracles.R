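# Independent oracles used across the suite. These compute expected
# values from first principles, deliberately avoiding the package's own
# formula-assembly code paths.

# monoisotopic masses, typed independently of the package's table
ORACLE_MONO <- c(C = 12, H = 1.00782503, N = 14.00307401, O = 15.99491462,
                 S = 31.97207069)
ORACLE_NOMINAL <- c(C = 12, H = 1, N = 14, O = 16, S = 32)

# mass of CcHhOoSs by direct arithmetic
oracle_mass <- function(c = 0, h = 0, o = 0, s = 0, table = ORACLE_MONO) {
  c * table[["C"]] + h * table[["H"]] + o * table[["O"]] + s * table[["S"]]
}

# neutral sulfolipid composition: core C9H18O10S + per chain
# (CnH(2n-2d)O2 - H2O); returns c(C, H, O, S)
oracle_species_atoms <- function(chains) {
  atoms <- c(C = 9, H = 18, O = 10, S = 1)
  for (ch in chains) {
    n <- as.integer(sub(":.*", "", ch))
    d <- as.integer(sub(".*:", "", ch))
    atoms <- atoms + c(C = n, H = 2 * n - 2 * d - 2, O = 1, S = 0)
  }
  atoms
}

oracle_mz_nominal <- function(chains) {
  a <- oracle_species_atoms(chains)
  oracle_mass(a[["C"]], a[["H"]], a[["O"]], a[["S"]], ORACLE_NOMINAL) - 1
}

oracle_mz_mono <- function(chains) {
  a <- oracle_species_atoms(chains)
  oracle_mass(a[["C"]], a[["H"]], a[["O"]], a[["S"]]) - ORACLE_MONO[["H"]]
}

DEFAULT_POOL_CHAINS <- c(
  "14:0", "15:0", "16:0", "16:1", "17:0", "18:0", "18:1",
  "18:2", "18:3", "18:4", "20:4", "20:5", "22:6"
)

# exhaustive enumeration oracle: all unordered pairs (SQDG) or singles
# (SQMG) from the pool at a nominal [M-H]- value, as sorted "a|b" keys
oracle_enumerate_keys <- function(precursor_nominal, lipid_class,
                                  pool = DEFAULT_POOL_CHAINS) {
  keys <- character()
  if (lipid_class == "SQMG") {
    for (ch in pool) {
      if (oracle_mz_nominal(ch) == precursor_nominal) {
        keys <- c(keys, ch)
      }
    }
  } else {
    np <- length(pool)
    for (i in seq_len(np)) for (j in i:np) {
      if (oracle_mz_nominal(c(pool[i], pool[j])) == precursor_nominal) {
        keys <- c(keys, paste(sort(c(pool[i], pool[j])), collapse = "|"))
      }
    }
  }
  sort(unique(keys))
}

species_keys <- function(species) {
  vapply(seq_len(nrow(species)), function(i) {
    ch <- c(species$chain1[i], species$chain2[i])
    ch <- ch[!is.na(ch)]
    paste(sort(ch), collapse = "|")
  }, character(1))
}

# single-channel Gaussian trace on a flat baseline
gaussian_trace <- function(apex = 20.5, sigma = 0.1, area = 1e5,
                           from = 15, to = 25, dt = 0.01,
                           baseline = 0, id = "trace") {
  t <- seq(from, to, by = dt)
  tibble::tibble(
    transition_id = id,
    time_min = t,
    intensity = baseline + area * stats::dnorm(t, apex, sigma)
  )
}
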