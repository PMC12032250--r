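# Independent brute-force oracles for the inheritance engine. These
# re-derive gamete, cross and one-generation allele-frequency distributions
# by explicit enumeration of elementary events (homologue choice, conversion
# fate, recombination, mating pairs), deliberately sharing no code with the
# package implementation.

ALL_DRIVE <- c("W", "D", "R1", "R2")
ALL_EFF <- c("C", "E", "CR")
ALL_HAPS <- as.vector(outer(ALL_DRIVE, ALL_EFF, paste, sep = ":"))

# Enumerate the gamete distribution of one individual event-by-event.
oracle_gamete <- function(drive, effector, sex, p) {
  h <- if (sex == "female") p$homing_female else p$homing_male
  out <- setNames(numeric(length(ALL_HAPS)), ALL_HAPS)
  add <- function(d, e, pr) {
    key <- paste(d, e, sep = ":")
    out[key] <<- out[key] + pr
  }
  drive_het <- ("D" %in% drive) && ("W" %in% drive)
  eff_het <- ("D" %in% drive) && ("E" %in% effector) && ("C" %in% effector)
  r <- p$recombination_fraction

  # fate table of each homologue's drive allele after germline conversion
  drive_fates <- function(i) {
    a <- drive[i]
    if (drive_het && a == "W") {
      if (r == 0.5) {
        # unlinked: work directly with the transmission-level marginal,
        # folding the homologue choice in (see below)
        NULL
      } else {
        list(list(al = "D", pr = 2 * h - 1),
             list(al = "W", pr = 2 * (1 - h) * p$uncut_fraction),
             list(al = "R1", pr = 2 * (1 - h) * (1 - p$uncut_fraction) *
                    p$functional_fraction),
             list(al = "R2", pr = 2 * (1 - h) * (1 - p$uncut_fraction) *
                    (1 - p$functional_fraction)))
      }
    } else list(list(al = a, pr = 1))
  }
  eff_fates <- function(i) {
    a <- effector[i]
    if (eff_het && a == "C" && r != 0.5) {
      hE <- p$effector_homing; uE <- p$effector_uncut_fraction
      list(list(al = "E", pr = 2 * hE - 1),
           list(al = "C", pr = 2 * (1 - hE) * uE),
           list(al = "CR", pr = 2 * (1 - hE) * (1 - uE)))
    } else list(list(al = a, pr = 1))
  }

  if (r == 0.5) {
    # independent loci: enumerate transmitted drive allele and effector
    # allele marginals separately, then all pairs
    dmarg <- setNames(numeric(4L), ALL_DRIVE)
    if (drive_het) {
      u <- p$uncut_fraction; f <- p$functional_fraction
      dmarg["D"] <- h
      dmarg["W"] <- (1 - h) * u
      dmarg["R1"] <- (1 - h) * (1 - u) * f
      dmarg["R2"] <- (1 - h) * (1 - u) * (1 - f)
    } else for (i in 1:2) dmarg[drive[i]] <- dmarg[drive[i]] + 0.5
    emarg <- setNames(numeric(3L), ALL_EFF)
    if (eff_het) {
      hE <- p$effector_homing; uE <- p$effector_uncut_fraction
      emarg["E"] <- hE
      emarg["C"] <- (1 - hE) * uE
      emarg["CR"] <- (1 - hE) * (1 - uE)
    } else for (i in 1:2) emarg[effector[i]] <- emarg[effector[i]] + 0.5
    for (d in ALL_DRIVE) for (e in ALL_EFF)
      if (dmarg[d] * emarg[e] > 0) add(d, e, dmarg[d] * emarg[e])
    return(out)
  }

  # linked loci: enumerate homologue sources and conversion fates
  for (i in 1:2) for (j in 1:2) {
    w_src <- 0.5 * (if (i == j) 1 - r else r)
    for (df in drive_fates(i)) for (ef in eff_fates(j)) {
      pr <- w_src * df$pr * ef$pr
      if (pr > 0) add(df$al, ef$al, pr)
    }
  }
  out
}

# Cross distribution by explicit enumeration of gamete pairs, collapsed onto
# canonical genotype labels.
oracle_cross <- function(m_drive, m_eff, f_drive, f_eff, p) {
  gm <- oracle_gamete(m_drive, m_eff, "female", p)
  gf <- oracle_gamete(f_drive, f_eff, "male", p)
  acc <- list()
  for (i in seq_along(gm)) for (j in seq_along(gf)) {
    pr <- gm[[i]] * gf[[j]]
    if (pr == 0) next
    key <- paste(sort(c(names(gm)[i], names(gf)[j])), collapse = "/")
    acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + pr
  }
  unlist(acc)[order(names(acc))]
}

# One-generation allele-frequency update by enumeration of all mating pairs.
oracle_step <- function(freqs, p, weights = c(functional = 1,
                                              heterozygous_LOF = 1,
                                              homozygous_LOF = 1)) {
  genos <- list()
  for (i in seq_along(ALL_DRIVE)) for (j in i:length(ALL_DRIVE)) {
    a <- c(ALL_DRIVE[i], ALL_DRIVE[j])
    f <- if (i == j) freqs[[a[1]]]^2 else 2 * freqs[[a[1]]] * freqs[[a[2]]]
    cls <- c("functional", "heterozygous_LOF",
             "homozygous_LOF")[sum(a %in% c("D", "R2")) + 1]
    genos[[length(genos) + 1]] <- list(a = a, f = f * weights[[cls]])
  }
  tot <- sum(vapply(genos, `[[`, numeric(1), "f"))
  next_f <- setNames(numeric(4), ALL_DRIVE)
  for (mo in genos) for (fa in genos) {
    w <- (mo$f / tot) * (fa$f / tot)
    if (w == 0) next
    gm <- oracle_gamete(mo$a, c("C", "C"), "female", p)
    gf <- oracle_gamete(fa$a, c("C", "C"), "male", p)
    for (d in ALL_DRIVE) {
      pm <- sum(gm[paste(d, ALL_EFF, sep = ":")])
      pf <- sum(gf[paste(d, ALL_EFF, sep = ":")])
      next_f[d] <- next_f[d] + w * 0.5 * (pm + pf)
    }
  }
  next_f / sum(next_f)
}

# All unordered genotype combinations at both loci.
all_drive_pairs <- function() {
  out <- list()
  for (i in seq_along(ALL_DRIVE)) for (j in i:length(ALL_DRIVE))
    out[[length(out) + 1]] <- c(ALL_DRIVE[i], ALL_DRIVE[j])
  out
}

all_eff_pairs <- function() {
  out <- list()
  for (i in seq_along(ALL_EFF)) for (j in i:length(ALL_EFF))
    out[[length(out) + 1]] <- c(ALL_EFF[i], ALL_EFF[j])
  out
}

# Random valid parameter draw; homing >= 0.5 so the linked (conversion)
# mechanism is defined for every genotype.
random_params <- function() {
  drive_params(homing_female = runif(1, 0.5, 1),
               homing_male = runif(1, 0.5, 1),
               uncut_fraction = runif(1),
               functional_fraction = runif(1),
               effector_homing = runif(1, 0.5, 1),
               effector_uncut_fraction = runif(1),
               recombination_fraction = runif(1, 0, 0.5))
}

# Align a package distribution with an oracle distribution on the union of
# their supports and return the maximum absolute difference.
max_dist_diff <- function(a, b) {
  keys <- union(names(a), names(b))
  av <- setNames(numeric(length(keys)), keys); av[names(a)] <- a
  bv <- setNames(numeric(length(keys)), keys); bv[names(b)] <- b
  max(abs(av - bv))
}
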