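#' Default haplotype frequency vector for the synthetic cohort
#'
#' The eight-haplotype frequency vector observed in the study population
#' (fractions summing to 1): the two common haplotypes A1-A3 and B1-A3
#' carry ~82\% of chromosomes, with A1-C3 and B1-C3 intermediate and the
#' remaining four rare.
#'
#' @return Named numeric vector of haplotype frequencies.
#' @export
default_hap_freqs <- function() {
  c("A1-A3" = 0.3623, "A1-B3" = 0.0053, "A1-C3" = 0.1016,
    "B1-A3" = 0.4591, "B1-B3" = 0.0147, "B1-C3" = 0.0556,
    "D1-A3" = 0.0007, "D1-C3" = 0.0007)
}

# Per-trait generation parameters: intercept, male effect, rearing/birth
# rank effects, sire SD and residual SD, in the trait's own units.
default_trait_params <- function() {
  list(
    birth_weight = list(intercept = 5.9, male = 0.3,
                        rank = c(single = 0, twin = -0.7, triplet = -1.4),
                        rank_var = "birth_rank", sire_sd = 0.15,
                        resid_sd = 0.9),
    growth_rate = list(intercept = 285, male = 12,
                       rank = c(single = 0, twin = -28, triplet = -55),
                       rank_var = "rearing_rank", sire_sd = 8,
                       resid_sd = 55),
    vgr = list(intercept = 3.0, male = 0,
               rank = c(single = 0, twin = -0.2, triplet = -0.4),
               rank_var = "rearing_rank", sire_sd = 0.5, resid_sd = 1.7),
    leg_yield = list(intercept = 20.8, male = 0,
                     rank = c(single = 0, twin = -0.15, triplet = -0.3),
                     rank_var = "rearing_rank", sire_sd = 0.25,
                     resid_sd = 1.2),
    loin_yield = list(intercept = 14.2, male = 0,
                      rank = c(single = 0, twin = -0.1, triplet = -0.2),
                      rank_var = "rearing_rank", sire_sd = 0.18,
                      resid_sd = 0.9),
    shoulder_yield = list(intercept = 16.7, male = 0,
                          rank = c(single = 0, twin = -0.1, triplet = -0.2),
                          rank_var = "rearing_rank", sire_sd = 0.2,
                          resid_sd = 1.0)
  )
}

# Haplotype presence effects planted in the default cohort, chosen to echo
# the direction and magnitude of the associations the pipeline is built to
# detect: A1-A3 depresses growth and leg/loin yield, A1-C3 raises fat depth.
default_hap_effects <- function() {
  list(
    "A1-A3" = c(growth_rate = -8, leg_yield = -0.45, loin_yield = -0.18),
    "A1-C3" = c(vgr = 1.4)
  )
}

#' Configuration for the synthetic half-sib cohort generator
#'
#' Captures every parameter of the simulated cohort: family structure,
#' haplotype pool, per-trait generation parameters, planted haplotype
#' effects, the slaughter selection rule and the seed.  The seed is
#' mandatory -- the generator has no implicit entropy.
#'
#' @param seed integer RNG seed (mandatory).
#' @param n_sires number of independent sire lines (default 17).
#' @param n_progeny total genotyped progeny, distributed as evenly as
#'   possible across sires (default 1185).
#' @param hap_freqs named haplotype frequency vector summing to 1
#'   (default [default_hap_freqs()]).
#' @param trait_params per-trait generation parameters; see
#'   `sirehap:::default_trait_params()` for the expected shape.
#' @param hap_effects named list: haplotype -> named vector of per-trait
#'   presence effects (default plants a growth/yield effect on A1-A3 and a
#'   fat-depth effect on A1-C3).
#' @param effect_mode `"presence"` (0/1 carrier coding, default) or
#'   `"additive"` (0/1/2 dosage) for how haplotype effects enter traits.
#' @param slaughter_weight live-weight threshold (kg) above which males are
#'   slaughtered and acquire carcass phenotypes (default 36).
#' @param post_weaning_gain post-weaning live-weight gain, kg/day
#'   (default 0.23).
#' @param missing_rate independent missingness probability applied to each
#'   phenotype cell (default 0).
#' @param genotype_error_rate per-region probability that one allele of an
#'   observed genotype is mislabelled (default 0; exercises the
#'   inconsistency path when positive).
#' @param include_sire_rows emit one row per sire carrying its true region
#'   genotypes (default TRUE).
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(seed,
                       n_sires = 17L,
                       n_progeny = 1185L,
                       hap_freqs = default_hap_freqs(),
                       trait_params = default_trait_params(),
                       hap_effects = default_hap_effects(),
                       effect_mode = c("presence", "additive"),
                       slaughter_weight = 36,
                       post_weaning_gain = 0.23,
                       missing_rate = 0,
                       genotype_error_rate = 0,
                       include_sire_rows = TRUE) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("config error: a seed is mandatory", call. = FALSE)
  }
  effect_mode <- match.arg(effect_mode)
  if (abs(sum(hap_freqs) - 1) > 1e-8 || any(hap_freqs < 0)) {
    stop("config error: haplotype frequencies must be non-negative and ",
         "sum to 1", call. = FALSE)
  }
  if (is.null(names(hap_freqs))) {
    stop("config error: haplotype frequencies must be named", call. = FALSE)
  }
  for (tp in trait_params) {
    if (tp$sire_sd < 0 || tp$resid_sd < 0) {
      stop("config error: SDs must be non-negative", call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), n_sires = as.integer(n_sires),
                 n_progeny = as.integer(n_progeny), hap_freqs = hap_freqs,
                 trait_params = trait_params, hap_effects = hap_effects,
                 effect_mode = effect_mode,
                 slaughter_weight = slaughter_weight,
                 post_weaning_gain = post_weaning_gain,
                 missing_rate = missing_rate,
                 genotype_error_rate = genotype_error_rate,
                 include_sire_rows = include_sire_rows),
            class = "sim_config")
}

#' Generate a synthetic half-sib cohort with known truth
#'
#' Simulates the cohort structure the pipeline targets: each sire receives
#' two haplotypes drawn from the population frequency vector; each progeny
#' inherits one sire haplotype uniformly and one dam haplotype drawn
#' i.i.d. from the same pool (dams are an unmodelled population).  Traits
#' follow `intercept + haplotype effects + gender + rank + sire deviation
#' + residual`, with pre-weaning growth rate and birth weight primary and
#' weaning weight derived from them so the growth-rate definition holds
#' exactly; leg/loin/shoulder yields are primary and total/proportion
#' yields derived via [derive_composition()].  Males whose simulated live
#' weight exceeds the slaughter threshold acquire carcass phenotypes;
#' females and light males do not.  Observed genotypes are the region-wise
#' collapse of the true diplotype, optionally perturbed by a mislabel
#' rate.
#'
#' All randomness flows from `config$seed` through a local RNG stream (the
#' caller's RNG state is untouched), so the same configuration always
#' yields a byte-identical cohort.
#'
#' @param config a [sim_config()].
#' @return An object of class `"sim_cohort"`: list with
#'   \describe{
#'     \item{records}{animal table in the exact schema
#'       [read_animal_table()] consumes (sire rows first when emitted);}
#'     \item{truth}{data frame of latent values per progeny: true
#'       diplotype, sire/dam haplotype, sire diplotype, live weight;}
#'     \item{config}{the configuration used.}
#'   }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(config$seed)

  haps <- names(config$hap_freqs)
  reg <- variant_registry()
  ns <- config$n_sires
  np <- config$n_progeny

  sire_ids <- sprintf("S%02d", seq_len(ns))
  sire_h1 <- sample(haps, ns, replace = TRUE, prob = config$hap_freqs)
  sire_h2 <- sample(haps, ns, replace = TRUE, prob = config$hap_freqs)
  sire_dip <- diplotype(sire_h1, sire_h2)

  base <- np %/% ns
  fam_sizes <- rep(base, ns) + c(rep(1L, np - base * ns),
                                 rep(0L, ns - (np - base * ns)))
  sire_of <- rep(seq_len(ns), fam_sizes)

  take_first <- stats::runif(np) < 0.5
  hap_sire <- ifelse(take_first, sire_h1[sire_of], sire_h2[sire_of])
  hap_dam <- sample(haps, np, replace = TRUE, prob = config$hap_freqs)
  dip <- diplotype(hap_sire, hap_dam)

  gender <- sample(c("male", "female"), np, replace = TRUE)
  birth_rank <- sample(c("single", "twin", "triplet"), np, replace = TRUE,
                       prob = c(0.25, 0.55, 0.20))
  demote <- c(single = "single", twin = "single", triplet = "twin")
  rearing_rank <- ifelse(stats::runif(np) < 0.12,
                         demote[birth_rank], birth_rank)
  age_weaning <- pmax(60, round(stats::rnorm(np, 95, 6)))

  dosage <- function(h) {
    hm <- dip_haps(dip)
    d <- (hm[, "hap1"] == h) + (hm[, "hap2"] == h)
    if (config$effect_mode == "presence") as.numeric(d > 0) else as.numeric(d)
  }
  hap_term <- function(trait) {
    out <- numeric(np)
    for (h in names(config$hap_effects)) {
      eff <- config$hap_effects[[h]]
      if (trait %in% names(eff)) out <- out + eff[[trait]] * dosage(h)
    }
    out
  }
  gen_trait <- function(trait, idx = seq_len(np)) {
    tp <- config$trait_params[[trait]]
    sire_dev <- stats::rnorm(ns, 0, tp$sire_sd)
    rank <- if (tp$rank_var == "birth_rank") birth_rank else rearing_rank
    y <- tp$intercept +
      tp$male * (gender == "male") +
      tp$rank[rank] +
      hap_term(trait) +
      sire_dev[sire_of] +
      stats::rnorm(np, 0, tp$resid_sd)
    unname(y[idx])
  }

  birth_weight <- gen_trait("birth_weight")
  growth_rate <- gen_trait("growth_rate")
  weaning_weight <- birth_weight + growth_rate * age_weaning / 1000
  tailing_weight <- birth_weight + growth_rate * 21 / 1000 +
    stats::rnorm(np, 0, 0.5)

  days_post <- pmax(40, round(stats::rnorm(np, 110, 15)))
  live_weight <- weaning_weight + config$post_weaning_gain * days_post
  slaughtered <- gender == "male" & live_weight > config$slaughter_weight
  age_slaughter <- ifelse(slaughtered, age_weaning + days_post, NA_real_)

  vgr <- leg <- loin <- shoulder <- hcw <- rep(NA_real_, np)
  idx <- which(slaughtered)
  if (length(idx)) {
    vgr_all <- gen_trait("vgr")
    leg_all <- gen_trait("leg_yield")
    loin_all <- gen_trait("loin_yield")
    shoulder_all <- gen_trait("shoulder_yield")
    vgr[idx] <- pmax(0.1, vgr_all[idx])
    leg[idx] <- pmax(1, leg_all[idx])
    loin[idx] <- pmax(1, loin_all[idx])
    shoulder[idx] <- pmax(1, shoulder_all[idx])
    hcw[idx] <- 0.42 * live_weight[idx] + stats::rnorm(length(idx), 0, 0.8)
  }
  comp <- data.frame(total_yield = rep(NA_real_, np), prop_leg = NA_real_,
                     prop_loin = NA_real_, prop_shoulder = NA_real_)
  if (length(idx)) {
    comp[idx, ] <- derive_composition(leg[idx], loin[idx], shoulder[idx])
  }

  # observed genotypes: region-wise collapse of the truth, with optional
  # per-region mislabelling to exercise the inconsistency path
  obs <- collapse_diplotype(dip)
  if (config$genotype_error_rate > 0) {
    perturb <- function(gt, legal) {
      hit <- stats::runif(np) < config$genotype_error_rate
      for (i in which(hit)) {
        al <- strsplit(gt[i], "/", fixed = TRUE)[[1L]]
        slot <- sample(2L, 1L)
        al[slot] <- sample(setdiff(legal, al[slot]), 1L)
        gt[i] <- paste(sort(al), collapse = "/")
      }
      gt
    }
    obs$genotype_prom <- perturb(obs$genotype_prom, reg$PROM_EX1)
    obs$genotype_coding <- perturb(obs$genotype_coding, reg$INT2_EX3)
  }

  animal_id <- sprintf("L%04d", seq_len(np))
  records <- data.frame(
    animal_id = animal_id, sire_id = sire_ids[sire_of], gender = gender,
    birth_rank = birth_rank, rearing_rank = rearing_rank,
    age_weaning = age_weaning, age_slaughter = age_slaughter,
    genotype_prom = obs$genotype_prom, genotype_coding = obs$genotype_coding,
    birth_weight = birth_weight, tailing_weight = tailing_weight,
    weaning_weight = weaning_weight, growth_rate = growth_rate,
    hot_carcass_weight = hcw, vgr = vgr,
    leg_yield = leg, loin_yield = loin, shoulder_yield = shoulder,
    total_yield = comp$total_yield, prop_leg = comp$prop_leg,
    prop_loin = comp$prop_loin, prop_shoulder = comp$prop_shoulder,
    stringsAsFactors = FALSE)

  if (config$missing_rate > 0) {
    pheno <- c("birth_weight", "tailing_weight", "weaning_weight",
               "growth_rate", "hot_carcass_weight", "vgr", "leg_yield",
               "loin_yield", "shoulder_yield")
    for (cn in pheno) {
      hit <- stats::runif(np) < config$missing_rate
      records[[cn]][hit] <- NA_real_
    }
    # keep the composition identities intact after knockout
    broken <- is.na(records$leg_yield) | is.na(records$loin_yield) |
      is.na(records$shoulder_yield)
    records[broken, c("total_yield", "prop_leg", "prop_loin",
                      "prop_shoulder")] <- NA_real_
  }

  if (config$include_sire_rows) {
    sire_obs <- collapse_diplotype(sire_dip)
    sire_rows <- records[0, , drop = FALSE][seq_len(ns), , drop = FALSE]
    sire_rows$animal_id <- sire_ids
    sire_rows$sire_id <- NA_character_
    sire_rows$gender <- "male"
    sire_rows$genotype_prom <- sire_obs$genotype_prom
    sire_rows$genotype_coding <- sire_obs$genotype_coding
    records <- rbind(sire_rows, records)
    rownames(records) <- NULL
  }

  truth <- data.frame(
    animal_id = animal_id, sire_id = sire_ids[sire_of],
    diplotype = dip, hap_sire = hap_sire, hap_dam = hap_dam,
    sire_diplotype = sire_dip[sire_of],
    live_weight = live_weight, slaughtered = slaughtered,
    stringsAsFactors = FALSE)

  structure(list(records = records, truth = truth, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Synthetic half-sib cohort:", nrow(x$truth), "progeny,",
      x$config$n_sires, "sires (seed", x$config$seed, ")\n")
  invisible(x)
}
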