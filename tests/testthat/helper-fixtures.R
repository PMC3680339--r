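# Shared fixtures and independent oracles, built in code at test time.

# 5-animal textbook pedigree: two founders, two full sibs, one offspring of
# the full-sib mating.
worked_pedigree <- function() {
  pedigree(c("s", "d", "a", "b", "x"),
           sire = c(NA, NA, "s", "s", "a"),
           dam = c(NA, NA, "d", "d", "b"))
}

# Random acyclic pedigree of n animals: each animal may take two distinct
# earlier animals as parents (or be a founder).
random_pedigree <- function(n, p_parent = 0.7) {
  sire <- dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i >= 3 && stats::runif(1) < p_parent) {
      par <- sample(i - 1L, 2L)
      sire[i] <- paste0("a", par[1])
      dam[i] <- paste0("a", par[2])
    }
  }
  pedigree(paste0("a", seq_len(n)), sire, dam)
}

# Independent kinship oracle: memoized recursive coancestry.
# phi(i,i) = (1 + phi(s_i, d_i)) / 2 ; phi(i,j) = (phi(s_i,j) + phi(d_i,j))/2
# for i ordered after j; unknown parents contribute 0.
kinship_oracle <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  phi <- matrix(NA_real_, n, n)
  get_phi <- function(i, j) {
    if (i == 0 || j == 0) return(0)
    if (!is.na(phi[i, j])) return(phi[i, j])
    v <- if (i == j) {
      s <- if (is.na(si[i])) 0L else si[i]
      d <- if (is.na(di[i])) 0L else di[i]
      0.5 * (1 + get_phi(s, d))
    } else {
      a <- max(i, j); b <- min(i, j)   # a is the later-born animal
      s <- if (is.na(si[a])) 0L else si[a]
      d <- if (is.na(di[a])) 0L else di[a]
      0.5 * (get_phi(s, b) + get_phi(d, b))
    }
    phi[i, j] <<- v
    phi[j, i] <<- v
    v
  }
  out <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) for (j in seq_len(i)) {
    out[i, j] <- out[j, i] <- get_phi(i, j)
  }
  out
}

# A medium synthetic herd shared by the slower genetics tests; built once
# per test run.
.herd_cache <- new.env(parent = emptyenv())
shared_herd <- function() {
  if (!is.null(.herd_cache$herd)) return(.herd_cache$herd)
  cfg <- sim_config(n_sires = 50, offspring_per_sire_range = c(15, 25),
                    n_dams = 400, n_chromosomes = 6,
                    snps_per_chromosome = 170,
                    missing_genotype_rate = 0.005, seed = 42)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  arch <- trait_architecture(geno, cfg)
  phen <- simulate_phenotypes(ped, geno, arch, cfg)
  .herd_cache$herd <- list(cfg = cfg, ped = ped, geno = geno, arch = arch,
                           phen = phen)
  .herd_cache$herd
}

# Small genotype fixture with known dosages.
toy_genotypes <- function(dosage, chr = NULL, pos = NULL) {
  dosage <- as.matrix(dosage)
  p <- ncol(dosage)
  map <- data.frame(snp = paste0("m", seq_len(p)),
                    chr = chr %||% rep("1", p),
                    pos = pos %||% seq(1e5, by = 1e5, length.out = p),
                    stringsAsFactors = FALSE)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("an", seq_len(nrow(dosage)))
  genotype_matrix(dosage, map)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
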