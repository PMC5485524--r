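test_that("candidate enumeration covers exactly the collapse-consistent diplotypes", {
  # homozygous in one region: phase is forced
  expect_equal(enumerate_candidate_diplotypes("A1/A1", "A3/B3"),
               "A1-A3/A1-B3")
  expect_equal(enumerate_candidate_diplotypes("A1/A1", "A3/A3"),
               "A1-A3/A1-A3")
  # double heterozygote: cis and trans pairings
  expect_setequal(enumerate_candidate_diplotypes("A1/B1", "A3/C3"),
                  c("A1-A3/B1-C3", "A1-C3/B1-A3"))

  # brute-force cross-check over every genotype pair in the default registry
  reg <- variant_registry()
  proms <- apply(expand.grid(reg$PROM_EX1, reg$PROM_EX1), 1, function(r) {
    paste(sort(r), collapse = "/")
  })
  cods <- apply(expand.grid(reg$INT2_EX3, reg$INT2_EX3), 1, function(r) {
    paste(sort(r), collapse = "/")
  })
  for (gp in unique(proms)) {
    for (gc in unique(cods)) {
      got <- enumerate_candidate_diplotypes(gp, gc)
      expect_setequal(got, oracle_pairings(gp, gc))
      # every candidate collapses back to the observed genotypes
      cl <- collapse_diplotype(got)
      expect_true(all(cl$genotype_prom == gp & cl$genotype_coding == gc))
      het <- !identical(substr(gp, 1, 2), substr(gp, 4, 5)) &&
        !identical(substr(gc, 1, 2), substr(gc, 4, 5))
      expect_length(got, if (het) 2L else 1L)
    }
  }
})

test_that("half/half transmission reconstructs a double-heterozygous sire", {
  # 5 progeny carrying A1-B3 and 6 carrying B1-C3, each directly phased
  # with a distinct dam haplotype
  dips <- c("A1-B3/A1-A3", "A1-B3/A1-C3", "A1-B3/A1-B3", "A1-B3/B1-B3",
            "A1-B3/D1-B3",
            "B1-C3/B1-A3", "B1-C3/B1-B3", "B1-C3/B1-C3", "B1-C3/A1-C3",
            "B1-C3/D1-C3", "B1-A3/B1-C3")
  cands <- lapply(dips, function(d) d)
  est <- reconstruct_sire_diplotype(cands)
  expect_false(est$ambiguous)
  expect_equal(est$chosen, "A1-B3/B1-C3")
})

test_that("a homozygous sire genotype forces the reconstruction", {
  cands <- rep(list("A1-A3/A1-A3"), 8)
  est <- reconstruct_sire_diplotype(
    cands, sire_genotypes = list(prom = "A1/A1", coding = "A3/A3"))
  expect_equal(est$chosen, "A1-A3/A1-A3")
  expect_false(est$ambiguous)
})

test_that("progeny resolution follows the shared-haplotype rule", {
  sire <- structure(list(chosen = "A1-A3/B1-C3", ambiguous = FALSE),
                    class = "sire_estimate")
  r <- resolve_progeny(c("A1-A3/B1-B3", "A1-B3/B1-A3"), sire)
  expect_equal(r$resolved, "A1-A3/B1-B3")
  expect_equal(r$method, "sire_informed")

  r <- resolve_progeny("A1-A3/A1-B3", sire)
  expect_equal(r$method, "direct")

  # both candidates share a sire haplotype: left unresolved, never guessed
  sire2 <- structure(list(chosen = "A1-A3/B1-A3", ambiguous = FALSE),
                     class = "sire_estimate")
  r <- resolve_progeny(c("A1-A3/B1-C3", "A1-C3/B1-A3"), sire2)
  expect_equal(r$method, "unresolved")
  expect_true(is.na(r$resolved))

  # no candidate shares a sire haplotype: Mendelian conflict
  sire3 <- structure(list(chosen = "D1-A3/D1-C3", ambiguous = FALSE),
                     class = "sire_estimate")
  r <- resolve_progeny(c("A1-A3/B1-C3", "A1-C3/B1-A3"), sire3)
  expect_equal(r$method, "inconsistent")
})

test_that("cohort phasing matches the exhaustive oracle on random families", {
  set.seed(77)
  n_agree <- 0L
  for (rep in 1:200) {
    fam <- random_family(n_max = 10)
    cands <- lapply(fam$gts, function(g) {
      enumerate_candidate_diplotypes(g[1], g[2])
    })
    est <- reconstruct_sire_diplotype(cands)
    ora <- oracle_sire(fam$gts)
    expect_identical(est$chosen, ora$chosen)
    expect_identical(est$ambiguous, ora$ambiguous)
    for (i in seq_along(fam$gts)) {
      got <- resolve_progeny(cands[[i]], est)
      exp <- oracle_resolve(fam$gts[[i]][1], fam$gts[[i]][2], ora$chosen)
      expect_identical(got$resolved, exp$resolved)
      expect_identical(got$method, exp$method)
      # a resolved progeny is never resolved wrongly when the sire was right
      if (!is.na(got$resolved) && identical(est$chosen, fam$sire_dip)) {
        expect_equal(got$resolved, fam$true_dip[i])
      }
    }
    if (!is.na(est$chosen)) n_agree <- n_agree + 1L
  }
  # the scenario space exercises both outcomes: some families reconstruct
  # uniquely, many small random families are legitimately ambiguous
  expect_gt(n_agree, 20L)
  expect_lt(n_agree, 200L)
})

test_that("phase_cohort resolves a seeded cohort correctly and deterministically", {
  fx <- assoc_fixture()
  co <- fx$cohort
  ph <- fx$phasing
  out <- ph$outcomes

  # every progeny is present; resolved diplotypes collapse to observations
  expect_equal(sort(out$animal_id), sort(co$truth$animal_id))
  res <- !is.na(out$resolved)
  cl <- collapse_diplotype(out$resolved[res])
  m <- match(out$animal_id[res], co$records$animal_id)
  expect_equal(cl$genotype_prom, co$records$genotype_prom[m])
  expect_equal(cl$genotype_coding, co$records$genotype_coding[m])

  # all resolutions and sire estimates equal the hidden truth
  tm <- match(out$animal_id, co$truth$animal_id)
  expect_true(all(out$resolved[res] == co$truth$diplotype[tm][res]))
  expect_gt(mean(res), 0.85)
  sd_true <- unique(co$truth[, c("sire_id", "sire_diplotype")])
  for (i in seq_len(nrow(sd_true))) {
    expect_equal(ph$sires[[sd_true$sire_id[i]]]$chosen,
                 sd_true$sire_diplotype[i])
  }

  # order invariance: a permuted cohort yields the same resolution map
  set.seed(9)
  perm <- co$records[sample(nrow(co$records)), , drop = FALSE]
  ph2 <- phase_cohort(perm)
  o2 <- ph2$outcomes[match(out$animal_id, ph2$outcomes$animal_id), ]
  expect_equal(o2$resolved, out$resolved)
  expect_equal(o2$method, out$method)
})

test_that("a genotype impossible under the sire flags only that progeny", {
  rows <- c(
    "animal_id,sire_id,gender,birth_rank,rearing_rank,genotype_prom,genotype_coding",
    "S01,,male,single,single,A1/A1,A3/A3",
    "L001,S01,male,twin,twin,A1/A1,A3/A3",
    "L002,S01,female,twin,twin,A1/B1,A3/A3",
    "L003,S01,male,single,single,B1/B1,B3/B3")
  tab <- read_animal_table(write_cohort_file(rows))
  ph <- phase_cohort(tab$records)
  out <- ph$outcomes
  expect_equal(out$method[out$animal_id == "L003"], "inconsistent")
  expect_equal(out$method[out$animal_id == "L001"], "direct")
  expect_equal(out$resolved[out$animal_id == "L002"], "A1-A3/B1-A3")
  expect_equal(ph$sires[["S01"]]$chosen, "A1-A3/A1-A3")
})

test_that("frequency estimation counts chromosomes and conserves mass", {
  ft <- estimate_frequencies(data.frame(
    resolved = c("A1-A3/A1-A3", "A1-A3/B1-A3")))
  expect_equal(ft$haplotypes$frequency[ft$haplotypes$haplotype == "A1-A3"],
               0.75)
  expect_equal(ft$haplotypes$frequency[ft$haplotypes$haplotype == "B1-A3"],
               0.25)
  expect_equal(ft$n_chromosomes, 4L)

  # all animals identical homozygotes
  ft1 <- estimate_frequencies(data.frame(resolved = rep("A1-A3/A1-A3", 5)))
  expect_equal(ft1$haplotypes$frequency, 1.0)

  expect_error(estimate_frequencies(data.frame(resolved = NA_character_)),
               "no resolved")

  # cohort-scale conservation: frequencies sum to 1, haplotype counts equal
  # the diplotype-multiplicity sums, and the estimate is exact on the
  # resolved subset
  fx <- assoc_fixture()
  ft2 <- estimate_frequencies(fx$phasing$outcomes)
  expect_equal(sum(ft2$haplotypes$frequency), 1, tolerance = 1e-12)
  expect_equal(sum(ft2$diplotypes$frequency), 1, tolerance = 1e-12)
  mult <- sapply(ft2$haplotypes$haplotype, function(h) {
    hm <- dip_haps(ft2$diplotypes$diplotype)
    sum(((hm[, 1] == h) + (hm[, 2] == h)) * ft2$diplotypes$count)
  })
  expect_equal(ft2$haplotypes$count, unname(mult))

  out <- fx$phasing$outcomes
  res <- !is.na(out$resolved)
  tm <- match(out$animal_id, fx$cohort$truth$animal_id)
  true_res <- fx$cohort$truth$diplotype[tm][res]
  ft_true <- estimate_frequencies(data.frame(resolved = true_res))
  expect_equal(ft2$haplotypes, ft_true$haplotypes)

  # exclusion can shift frequencies by at most the unresolved fraction
  u <- mean(!res)
  all_tr <- c(fx$cohort$truth$hap_sire, fx$cohort$truth$hap_dam)
  realized <- table(all_tr) / length(all_tr)
  for (h in names(realized)) {
    est <- ft2$haplotypes$frequency[ft2$haplotypes$haplotype == h]
    if (!length(est)) est <- 0
    expect_lt(abs(est - as.numeric(realized[[h]])), u + 1e-12)
  }
})

test_that("an orphan progeny is an integrity error", {
  rows <- c(
    "animal_id,sire_id,gender,birth_rank,rearing_rank,genotype_prom,genotype_coding",
    "L001,S01,male,twin,twin,A1/A1,A3/A3",
    "L002,,male,twin,twin,A1/A1,A3/A3")
  tab <- read_animal_table(write_cohort_file(rows))
  expect_error(phase_cohort(tab$records), "unknown sire")
})
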