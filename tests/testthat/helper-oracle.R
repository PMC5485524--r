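# Brute-force phasing oracle, written independently of the package's
# phasing code: it enumerates every diplotype over the observed variants
# and scores each by explicit loops.  Haplotypes are built by direct string
# pasting; nothing below calls the package's enumeration, reconstruction or
# resolution functions.

oracle_pairings <- function(gp, gc) {
  p <- strsplit(gp, "/", fixed = TRUE)[[1]]
  k <- strsplit(gc, "/", fixed = TRUE)[[1]]
  mk <- function(h1, h2) paste(sort(c(h1, h2)), collapse = "/")
  unique(c(mk(paste0(p[1], "-", k[1]), paste0(p[2], "-", k[2])),
           mk(paste0(p[1], "-", k[2]), paste0(p[2], "-", k[1]))))
}

oracle_dip_haps <- function(dip) strsplit(dip, "/", fixed = TRUE)[[1]]

oracle_shares <- function(dip, haps) {
  any(oracle_dip_haps(dip) %in% haps)
}

# Enumerate all sire diplotypes over the observed variants (or from the
# sire's own genotypes), filter by consistency with every progeny, score by
# direct-progeny support.  Returns list(chosen, ambiguous, consistent).
oracle_sire <- function(progeny_gts, sire_gts = NULL) {
  prog_cands <- lapply(progeny_gts, function(g) oracle_pairings(g[1], g[2]))

  if (!is.null(sire_gts)) {
    cand <- oracle_pairings(sire_gts[1], sire_gts[2])
  } else {
    haps <- sort(unique(unlist(lapply(prog_cands, function(cs) {
      unlist(lapply(cs, oracle_dip_haps))
    }))))
    cand <- character()
    for (a in seq_along(haps)) {
      for (b in a:length(haps)) {
        cand <- c(cand, paste(sort(c(haps[a], haps[b])), collapse = "/"))
      }
    }
    cand <- sort(unique(cand))
  }

  ok <- function(pc, sd) {
    sh <- oracle_dip_haps(sd)
    any(vapply(pc, function(d) oracle_shares(d, sh), logical(1)))
  }
  # progeny that fit no candidate are set aside (genotyping error path)
  fits_any <- vapply(prog_cands, function(pc) {
    any(vapply(cand, function(sd) ok(pc, sd), logical(1)))
  }, logical(1))
  usable <- prog_cands[fits_any]

  consistent <- cand[vapply(cand, function(sd) {
    all(vapply(usable, function(pc) ok(pc, sd), logical(1)))
  }, logical(1))]

  support <- vapply(cand, function(sd) {
    sh <- oracle_dip_haps(sd)
    sum(vapply(prog_cands, function(pc) {
      length(pc) == 1 && oracle_shares(pc[[1]], sh)
    }, logical(1)))
  }, numeric(1))

  chosen <- NA_character_
  ambiguous <- TRUE
  if (length(consistent)) {
    s <- support[consistent]
    best <- consistent[s == max(s)]
    if (length(best) == 1) {
      chosen <- best
      ambiguous <- FALSE
    }
  }
  list(chosen = chosen, ambiguous = ambiguous, consistent = consistent,
       inconsistent_progeny = which(!fits_any))
}

# Resolve one progeny given the oracle's sire diplotype.
oracle_resolve <- function(gp, gc, sire_dip) {
  cands <- oracle_pairings(gp, gc)
  if (length(cands) == 1) {
    return(list(resolved = cands, method = "direct"))
  }
  if (is.na(sire_dip)) {
    return(list(resolved = NA_character_, method = "unresolved"))
  }
  sh <- oracle_dip_haps(sire_dip)
  keep <- cands[vapply(cands, function(d) oracle_shares(d, sh), logical(1))]
  if (length(keep) == 1) {
    list(resolved = keep, method = "sire_informed")
  } else if (length(keep) == 0) {
    list(resolved = NA_character_, method = "inconsistent")
  } else {
    list(resolved = NA_character_, method = "unresolved")
  }
}

# Random half-sib family for property tests: a few variants per region,
# random haplotype pool frequencies, a random sire diplotype, <= n_max
# progeny each built from one sire and one dam haplotype.
random_family <- function(n_max = 10) {
  prom <- sample(c("A1", "B1", "C1", "D1"), sample(2:4, 1))
  coding <- sample(c("A3", "B3", "C3"), sample(2:3, 1))
  pool <- as.vector(outer(prom, coding, function(a, b) paste0(a, "-", b)))
  w <- stats::rexp(length(pool))
  sire <- sample(pool, 2, replace = TRUE, prob = w)
  n <- sample(2:n_max, 1)
  hap_s <- sample(sire, n, replace = TRUE)
  hap_d <- sample(pool, n, replace = TRUE, prob = w)
  gts <- lapply(seq_len(n), function(i) {
    ps <- strsplit(hap_s[i], "-", fixed = TRUE)[[1]]
    pd <- strsplit(hap_d[i], "-", fixed = TRUE)[[1]]
    c(paste(sort(c(ps[1], pd[1])), collapse = "/"),
      paste(sort(c(ps[2], pd[2])), collapse = "/"))
  })
  list(sire_dip = paste(sort(sire), collapse = "/"), gts = gts,
       true_dip = vapply(seq_len(n), function(i) {
         paste(sort(c(hap_s[i], hap_d[i])), collapse = "/")
       }, character(1)))
}
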