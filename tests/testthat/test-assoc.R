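test_that("presence coding marks carriers regardless of dose", {
  expect_equal(code_presence("A1-A3/A1-A3", "A1-A3"), 1L)
  expect_equal(code_presence("A1-A3/B1-A3", "B1-C3"), 0L)
  expect_equal(code_presence(NA_character_, "A1-A3"), NA_integer_)

  # over the five common diplotype groups, presence of A1-A3 is 1 exactly
  # for the three groups whose name contains it
  groups <- c("A1-A3/A1-A3", "A1-A3/A1-C3", "A1-A3/B1-A3",
              "B1-A3/B1-A3", "B1-A3/B1-C3")
  expect_equal(code_presence(groups, "A1-A3"), c(1L, 1L, 1L, 0L, 0L))

  # conservation against the frequency table on a phased cohort
  fx <- assoc_fixture()
  ft <- estimate_frequencies(fx$phasing$outcomes)
  res <- fx$data$diplotype[!is.na(fx$data$diplotype)]
  for (h in ft$haplotypes$haplotype) {
    carriers <- sum(code_presence(res, h))
    hm <- dip_haps(ft$diplotypes$diplotype)
    from_dips <- sum(ft$diplotypes$count[hm[, 1] == h | hm[, 2] == h])
    expect_equal(carriers, from_dips)
  }
})

test_that("significance classification uses the strict 0.05 / 0.20 rules", {
  expect_equal(classify_significance(0.031), "significant")
  expect_equal(classify_significance(0.062), "trend")
  expect_equal(classify_significance(0.05), "trend")  # boundary is a trend
  expect_equal(classify_significance(0.20), "ns")
  expect_equal(classify_significance(c(0.049999, 0.199999)),
               c("significant", "trend"))
  expect_error(classify_significance(1.2), "0, 1")
  expect_error(classify_significance(-0.1), "0, 1")
})

test_that("derived effects convert marginal means to per-day and mass terms", {
  g <- derived_growth_effect(275.9, 268.2, 100)
  expect_equal(g$per_day, 7.7)
  expect_equal(g$cumulative, 770)
  g0 <- derived_growth_effect(250, 250, 100)
  expect_equal(g0$cumulative, 0)
  g2 <- derived_growth_effect(280.0, 268.5, 90)
  expect_equal(g2$per_day, 11.5)
  expect_equal(g2$cumulative, 1035)
  expect_error(derived_growth_effect(1, 2, 0), "positive")

  expect_equal(derived_meat_effect(0.71, 18), 128)
  expect_equal(derived_meat_effect(0, 18), 0)
  expect_equal(derived_meat_effect(0.45, 18), 81)
  expect_error(derived_meat_effect(1, 0), "positive")
})

test_that("the presence model recovers a planted effect and its groups", {
  fx <- assoc_fixture()
  r <- fit_presence_model(fx$data, "growth_rate", "A1-A3")

  # bookkeeping: groups partition the analyzed animals
  resolved <- fx$data$diplotype[!is.na(fx$data$diplotype) &
                                  is.finite(fx$data$growth_rate)]
  expect_equal(r$n_absent + r$n_present, length(resolved))
  expect_equal(r$n_present, sum(code_presence(resolved, "A1-A3")))
  expect_true(r$se_absent > 0 && r$se_present > 0)

  # planted -8 g/day presence effect recovered within 2 SE
  expect_lt(abs(r$effect - (-8)), 2 * r$effect_se)
  # marginal means straddle the effect in the same direction
  expect_equal(sign(r$emm_present - r$emm_absent), sign(r$effect))
})

test_that("degenerate traits yield flagged, non-crashing results", {
  fx <- assoc_fixture()
  d <- fx$data
  d$flat <- 3.14
  spec <- model_spec("flat", fixed_factors = c("gender", "birth_rank"))
  r <- fit_presence_model(d, "flat", "A1-A3", spec)
  expect_equal(r$emm_absent, 3.14)
  expect_equal(r$emm_present, 3.14)
  expect_equal(r$p_value, 1)
  expect_match(r$note, "zero variance")

  # a haplotype nobody carries is not estimable
  r2 <- fit_presence_model(d, "growth_rate", "C1-B3",
                           model_spec("growth_rate"))
  expect_equal(r2$n_present, 0)
  expect_match(r2$note, "not estimable")
})

test_that("the adjusted model with no co-fitted haplotypes reduces exactly", {
  fx <- assoc_fixture()
  single <- fit_presence_model(fx$data, "growth_rate", "A1-A3")
  adj <- fit_adjusted_model(fx$data, "growth_rate", "A1-A3", character())
  adj$model <- "single"
  expect_identical(adj, single)
})

test_that("co-fitting separates a true effect from a correlated null haplotype", {
  # A1-C3 has the planted fat-depth effect; B1-A3 has none but shares the
  # frequency structure.  The adjusted fit keeps the true effect within
  # 2 SE and the null haplotype stays non-significant.
  fx <- assoc_fixture()
  true_eff <- fit_adjusted_model(fx$data, "vgr", "A1-C3", "B1-A3")
  expect_lt(abs(true_eff$effect - 1.4), 2 * true_eff$effect_se)
  expect_equal(true_eff$model, "adjusted")
  expect_equal(true_eff$others, "B1-A3")
  null_eff <- fit_adjusted_model(fx$data, "vgr", "B1-A3", "A1-C3")
  expect_gt(null_eff$p_value, 0.05)
})

test_that("diplotype model filters by frequency, corrects pairwise tests and letters", {
  fx <- assoc_fixture()
  dr <- fit_diplotype_model(fx$data, "leg_yield")
  expect_s3_class(dr, "diplotype_result")

  # the frequency filter is computed on the analyzed (male, slaughtered,
  # phased) subset
  males <- fx$data[fx$data$gender %in% "male" &
                     is.finite(fx$data$leg_yield) &
                     !is.na(fx$data$diplotype), ]
  freq <- table(males$diplotype) / nrow(males)
  expect_setequal(dr$groups$diplotype, names(freq)[freq > 0.05])
  expect_equal(sum(dr$groups$n), sum(freq[freq > 0.05]) * nrow(males))

  # Bonferroni: adjusted p = raw p * k(k-1)/2, capped at 1
  k <- dr$k
  expect_equal(dr$pairwise$p_adj,
               pmin(1, dr$pairwise$p_raw * k * (k - 1) / 2))

  # letters are exactly reconstructible from the adjusted matrix: groups
  # share no letter iff adjusted p < alpha
  lab <- strsplit(dr$groups$letters, ",", fixed = TRUE)
  names(lab) <- dr$groups$diplotype
  for (r in seq_len(nrow(dr$pairwise))) {
    shared <- length(intersect(lab[[dr$pairwise$g1[r]]],
                               lab[[dr$pairwise$g2[r]]])) > 0
    expect_equal(shared, dr$pairwise$p_adj[r] >= 0.05)
  }
})

test_that("the compact letter display round-trips random p matrices", {
  set.seed(31)
  for (rep in 1:50) {
    k <- sample(3:7, 1)
    pm <- matrix(1, k, k, dimnames = list(paste0("g", 1:k), paste0("g", 1:k)))
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        pm[i, j] <- pm[j, i] <- sample(c(0.01, 0.2, 0.9), 1)
      }
    }
    lets <- strsplit(letter_display(pm, alpha = 0.05), ",", fixed = TRUE)
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        shared <- length(intersect(lets[[i]], lets[[j]])) > 0
        expect_equal(shared, pm[i, j] >= 0.05,
                     label = sprintf("rep %d pair (%d,%d) shared", rep, i, j))
      }
    }
  }
})

test_that("structure-term selection picks the biggest effect with a fixed tie rule", {
  set.seed(5)
  n <- 300
  d <- data.frame(
    gender = sample(c("male", "female"), n, replace = TRUE),
    birth_rank = sample(c("single", "twin", "triplet"), n, replace = TRUE),
    rearing_rank = sample(c("single", "twin", "triplet"), n, replace = TRUE),
    birth_weight = rnorm(n, 5.3, 0.8))
  rank_eff <- c(single = 0, twin = -30, triplet = -60)
  d$y <- 270 + rank_eff[d$birth_rank] + rnorm(n, 0, 10)
  sel <- select_structure_term(d, "y", mandatory = "gender")
  expect_equal(sel$term, "birth_rank")
  expect_equal(sel$note, "")

  # independent trait: still deterministic, flagged
  d$z <- rnorm(n, 100, 5)
  sel2 <- select_structure_term(d, "z", mandatory = "gender")
  expect_false(is.na(sel2$term))
  expect_equal(sel2$note, "no candidate p < 0.05")

  # constructed exact tie: rearing rank duplicates birth rank, so their F
  # statistics are identical and the fixed priority picks birth rank
  d2 <- d
  d2$rearing_rank <- d2$birth_rank
  d2$birth_weight <- rnorm(n, 5.3, 0.1)  # uninformative
  sel3 <- select_structure_term(d2, "y", mandatory = "gender")
  tabF <- sel3$table
  expect_equal(tabF$F[tabF$candidate == "birth_rank"],
               tabF$F[tabF$candidate == "rearing_rank"])
  expect_equal(sel3$term, "birth_rank")
})

test_that("model specs reject contradictory structure and bad thresholds", {
  expect_error(model_spec("y", fixed_factors = c("gender", "birth_rank"),
                          covariates = "birth_weight"),
               "mutually exclusive")
  expect_error(model_spec("y", alpha = 0), "thresholds")
  expect_error(model_spec("y", include_p = 1), "thresholds")
})

test_that("the haplotype series assembles single and adjusted tables coherently", {
  fx <- assoc_fixture()
  ser <- run_haplotype_series(fx$data, c("growth_rate", "vgr"))
  expect_true(all(ser$single$model == "single"))
  # common haplotypes only (frequency > 5%): A1-A3, B1-A3, A1-C3, B1-C3
  expect_true(all(ser$single$haplotype %in%
                    c("A1-A3", "B1-A3", "A1-C3", "B1-C3")))
  # the planted effects surface as sub-threshold single-model hits
  gr <- ser$single[ser$single$trait == "growth_rate", ]
  expect_lt(gr$p_value[gr$haplotype == "A1-A3"], 0.2)
  if (!is.null(ser$adjusted)) {
    expect_true(all(ser$adjusted$model == "adjusted"))
    expect_true(all(ser$adjusted$others != ""))
  }
})
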