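#' Presence/absence coding of a haplotype within a diplotype
#'
#' An animal scores 1 for a haplotype if its diplotype contains that
#' haplotype at least once -- homozygous and heterozygous carriers are both
#' coded 1, non-carriers 0 (a dominant-style coding).
#'
#' @param dip diplotype identifiers (vectorized; `NA` propagates).
#' @param hap a single haplotype identifier.
#' @return integer vector of 0/1 codes.
#' @examples
#' code_presence(c("A1-A3/A1-A3", "A1-A3/B1-A3", "B1-A3/B1-C3"), "A1-A3")
#' @export
code_presence <- function(dip, hap) {
  hap <- normalize_hap(hap)
  out <- rep(NA_integer_, length(dip))
  ok <- !is.na(dip)
  if (any(ok)) {
    hm <- dip_haps(dip[ok])
    out[ok] <- as.integer(hm[, "hap1"] == hap | hm[, "hap2"] == hap)
  }
  out
}

#' Significance classification
#'
#' Effects are declared significant when `p < 0.05`; a trend is noted when
#' `0.05 <= p < 0.20` (the boundary `p = 0.05` is classified as a trend,
#' honouring the strict `p < 0.05` rule); anything else is non-significant.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param alpha significance threshold (default 0.05).
#' @param trend_p upper bound of the trend band (default 0.20).
#' @return character vector: `"significant"`, `"trend"` or `"ns"`.
#' @examples
#' classify_significance(c(0.031, 0.062, 0.05, 0.5))
#' @export
classify_significance <- function(p, alpha = 0.05, trend_p = 0.20) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  ifelse(p < alpha, "significant", ifelse(p < trend_p, "trend", "ns"))
}

#' Model specification for one trait
#'
#' Bundles the fixed-factor structure, covariates and thresholds used by
#' the association models.  Birth rank (a factor) and birth weight as a
#' covariate encode the same litter-size information and are mutually
#' exclusive within one model.
#'
#' @param trait phenotype column name.
#' @param fixed_factors character vector drawn from `gender`, `birth_rank`,
#'   `rearing_rank`.
#' @param covariates character vector of numeric covariates (e.g.
#'   `age_weaning`, `age_slaughter`, `birth_weight`).
#' @param males_only restrict the analysis to males (carcass traits).
#' @param include_p single-model p-value below which a haplotype is
#'   co-fitted in the adjusted series (default 0.20).
#' @param alpha significance threshold (default 0.05).
#' @param diplotype_min_freq minimum diplotype frequency, on the analyzed
#'   subset, for inclusion in the diplotype model (default 0.05, strict).
#' @return An object of class `"model_spec"`.
#' @export
model_spec <- function(trait, fixed_factors = c("gender", "birth_rank"),
                       covariates = character(),
                       males_only = FALSE,
                       include_p = 0.20, alpha = 0.05,
                       diplotype_min_freq = 0.05) {
  if ("birth_rank" %in% fixed_factors && "birth_weight" %in% covariates) {
    stop("birth rank (factor) and birth weight (covariate) are mutually ",
         "exclusive in one model", call. = FALSE)
  }
  for (th in c(include_p, alpha, diplotype_min_freq)) {
    if (!is.numeric(th) || th <= 0 || th >= 1) {
      stop("thresholds must lie in (0, 1)", call. = FALSE)
    }
  }
  structure(list(trait = trait, fixed_factors = fixed_factors,
                 covariates = covariates, males_only = males_only,
                 include_p = include_p, alpha = alpha,
                 diplotype_min_freq = diplotype_min_freq),
            class = "model_spec")
}

#' Default per-trait model structure
#'
#' The factor structure used for each phenotype: birth weight is analysed
#' with gender and birth rank fixed; tailing and weaning weight with
#' gender, rearing rank and age at weaning; growth rate with gender and
#' rearing rank; carcass traits with rearing rank and age at slaughter on
#' males only.  Sire is always fitted as a random intercept.
#'
#' @return Named list of [model_spec()] objects, one per phenotype.
#' @export
default_trait_specs <- function() {
  growth <- function(trait, fixed, cov = character()) {
    model_spec(trait, fixed_factors = fixed, covariates = cov)
  }
  carcass <- function(trait) {
    model_spec(trait, fixed_factors = "rearing_rank",
               covariates = "age_slaughter", males_only = TRUE)
  }
  list(
    birth_weight = growth("birth_weight", c("gender", "birth_rank")),
    tailing_weight = growth("tailing_weight", c("gender", "rearing_rank"),
                            "age_weaning"),
    weaning_weight = growth("weaning_weight", c("gender", "rearing_rank"),
                            "age_weaning"),
    growth_rate = growth("growth_rate", c("gender", "rearing_rank")),
    hot_carcass_weight = carcass("hot_carcass_weight"),
    vgr = carcass("vgr"),
    leg_yield = carcass("leg_yield"),
    loin_yield = carcass("loin_yield"),
    shoulder_yield = carcass("shoulder_yield"),
    total_yield = carcass("total_yield"),
    prop_leg = carcass("prop_leg"),
    prop_loin = carcass("prop_loin"),
    prop_shoulder = carcass("prop_shoulder")
  )
}

#' Attach resolved diplotypes to animal records
#'
#' Joins a phasing result onto the records, adding a `diplotype` column
#' (`NA` for unresolved/inconsistent progeny and for sire rows) ready for
#' the association stage.
#'
#' @param records animal-record data frame.
#' @param phasing a `"phasing_result"`.
#' @return `records` with `diplotype` and `phase_method` columns added.
#' @export
assoc_dataset <- function(records, phasing) {
  m <- match(records$animal_id, phasing$outcomes$animal_id)
  records$diplotype <- phasing$outcomes$resolved[m]
  records$phase_method <- phasing$outcomes$method[m]
  records
}

# Build the analyzed model frame for one trait: subset, code terms, drop
# incomplete rows and degenerate terms.  Returns NULL plus a reason when
# the analysis is not estimable.
build_model_frame <- function(data, spec, need_diplotype = TRUE) {
  df <- data
  if (isTRUE(spec$males_only)) df <- df[df$gender %in% "male", , drop = FALSE]
  keep_cols <- unique(c(spec$trait, "diplotype", "sire_id",
                        spec$fixed_factors, spec$covariates))
  df <- df[, intersect(keep_cols, names(df)), drop = FALSE]
  ok <- is.finite(df[[spec$trait]])
  if (need_diplotype) ok <- ok & !is.na(df$diplotype)
  for (v in c(spec$fixed_factors, spec$covariates)) {
    ok <- ok & !is.na(df[[v]])
  }
  dropped <- sum(!ok)
  df <- df[ok, , drop = FALSE]

  factors <- character()
  for (v in spec$fixed_factors) {
    df[[v]] <- factor(df[[v]])
    if (nlevels(droplevels(df[[v]])) >= 2L) {
      df[[v]] <- droplevels(df[[v]])
      factors <- c(factors, v)
    }
  }
  covariates <- spec$covariates[vapply(spec$covariates, function(v) {
    stats::var(df[[v]]) > 0
  }, logical(1L))]
  df$sire_id <- factor(df$sire_id)
  attr(df, "dropped") <- dropped
  attr(df, "factors") <- factors
  attr(df, "covariates") <- covariates
  df
}

# Fit y ~ <terms> + (1|sire) by REML; collapse to fixed-effects-only lm
# when the sire variance estimate is zero/singular or only one sire is
# present.  Returns list(fit, sire_dropped).
fit_mixed <- function(formula_fixed, df) {
  rhs <- paste(deparse(formula_fixed[[3L]]), collapse = " ")
  if (nlevels(df$sire_id) >= 2L) {
    f <- stats::as.formula(paste(deparse(formula_fixed[[2L]]), "~", rhs,
                                 "+ (1 | sire_id)"))
    fit <- suppressWarnings(suppressMessages(
      lmerTest::lmer(f, data = df, REML = TRUE)))
    if (!lme4::isSingular(fit, tol = 1e-6)) {
      return(list(fit = fit, sire_dropped = FALSE))
    }
  }
  list(fit = stats::lm(formula_fixed, data = df), sire_dropped = TRUE)
}

# p-value for a single model coefficient, lmerTest (Satterthwaite) or lm.
coef_p <- function(fit, name) {
  ct <- stats::coef(summary(fit))
  if (!name %in% rownames(ct)) return(NA_real_)
  ct[name, ncol(ct)]
}

emm_table <- function(fit, term) {
  em <- emmeans::emmeans(fit, term, lmer.df = "satterthwaite")
  as.data.frame(em)
}

assoc_row <- function(trait, hap, model, others, n_absent, n_present,
                      emm_absent, se_absent, emm_present, se_present,
                      p_value, effect = NA_real_, effect_se = NA_real_,
                      note = "") {
  structure(data.frame(
    trait = trait, haplotype = hap, model = model,
    others = if (length(others)) paste(others, collapse = ",") else "",
    n_absent = n_absent, n_present = n_present,
    emm_absent = emm_absent, se_absent = se_absent,
    emm_present = emm_present, se_present = se_present,
    effect = effect, effect_se = effect_se,
    p_value = p_value, note = note, stringsAsFactors = FALSE),
    class = c("assoc_result", "data.frame"))
}

# Shared engine for the single and adjusted presence models.  The adjusted
# model with an empty co-fit set takes exactly this code path, so it
# reduces to the single model bit for bit.
fit_presence_core <- function(data, trait, haplotype, others, spec) {
  if (is.null(spec)) spec <- default_trait_specs()[[trait]]
  if (is.null(spec)) {
    stop("no model spec known for trait '", trait, "'", call. = FALSE)
  }
  df <- build_model_frame(data, spec)
  df$presence <- factor(code_presence(df$diplotype, haplotype),
                        levels = 0:1, labels = c("absent", "present"))
  tag <- if (length(others)) "adjusted" else "single"

  n_ab <- sum(df$presence == "absent")
  n_pr <- sum(df$presence == "present")
  if (n_ab == 0L || n_pr == 0L) {
    return(assoc_row(trait, haplotype, tag, others, n_ab, n_pr,
                     NA_real_, NA_real_, NA_real_, NA_real_, NA_real_,
                     note = "not estimable: a presence group is empty"))
  }
  if (stats::var(df[[trait]]) == 0) {
    const <- df[[trait]][1L]
    return(assoc_row(trait, haplotype, tag, others, n_ab, n_pr,
                     const, NA_real_, const, NA_real_, 1,
                     note = "zero variance in trait"))
  }

  co_terms <- character()
  for (h in others) {
    cn <- paste0("co_", gsub("[^A-Za-z0-9]", "_", h))
    v <- factor(code_presence(df$diplotype, h), levels = 0:1,
                labels = c("absent", "present"))
    if (nlevels(droplevels(v)) == 2L) {
      df[[cn]] <- v
      co_terms <- c(co_terms, cn)
    }
  }

  rhs <- c("presence", co_terms, attr(df, "factors"), attr(df, "covariates"))
  f <- stats::as.formula(paste(trait, "~", paste(rhs, collapse = " + ")))
  m <- fit_mixed(f, df)
  if (inherits(m$fit, "lm") && anyNA(stats::coef(m$fit)["presencepresent"])) {
    stop("singular fit: presence of ", haplotype,
         " is collinear with other model terms", call. = FALSE)
  }
  ct <- stats::coef(summary(m$fit))
  p <- coef_p(m$fit, "presencepresent")
  eff <- ct["presencepresent", "Estimate"]
  eff_se <- ct["presencepresent", "Std. Error"]
  em <- emm_table(m$fit, "presence")
  ab <- em[em$presence == "absent", ]
  pr <- em[em$presence == "present", ]
  note <- if (m$sire_dropped) "sire variance zero: fixed-effects fit" else ""
  out <- assoc_row(trait, haplotype, tag, others, n_ab, n_pr,
                   ab$emmean, ab$SE, pr$emmean, pr$SE, p,
                   effect = eff, effect_se = eff_se, note = note)
  attr(out, "dropped") <- attr(df, "dropped")
  out
}

#' Single-haplotype presence/absence association model
#'
#' Fits a linear mixed model for one trait with the haplotype's
#' presence/absence (0/1) as the term of interest, the trait's fixed
#' factors and covariates from its [model_spec()], and sire as a random
#' intercept estimated by REML (collapsing to a fixed-effects model when
#' the sire variance estimate is zero).  Reports estimated marginal means
#' (equal weights across fixed-factor levels, covariates at their means)
#' with standard errors for the absent and present groups, group sizes and
#' the presence-term p-value (Satterthwaite df).  Animals with a null
#' diplotype or missing trait/term values are dropped; the count is
#' available as `attr(result, "dropped")`.
#'
#' @param data association data frame, as from [assoc_dataset()].
#' @param trait phenotype column name.
#' @param haplotype focal haplotype identifier.
#' @param spec a [model_spec()]; defaults to [default_trait_specs()].
#' @return A one-row data frame of class `"assoc_result"`.
#' @export
fit_presence_model <- function(data, trait, haplotype, spec = NULL) {
  fit_presence_core(data, trait, haplotype, character(), spec)
}

#' Adjusted (multi-haplotype) association model
#'
#' Same contract as [fit_presence_model()], but the presence/absence of
#' each haplotype in `others` is co-fitted as an additional fixed term so
#' that the focal haplotype's effect is estimated net of correlated
#' haplotypes.  `others` is conventionally the set of haplotypes whose
#' single-haplotype p-value for this trait fell below the inclusion
#' threshold (0.20).  With an empty `others` the result is identical to
#' the single model.
#'
#' @inheritParams fit_presence_model
#' @param others character vector of co-fitted haplotype identifiers.
#' @return A one-row data frame of class `"assoc_result"` whose `model`
#'   tag is `"adjusted"` and whose `others` field records the co-fitted
#'   set.
#' @export
fit_adjusted_model <- function(data, trait, haplotype, others, spec = NULL) {
  others <- setdiff(normalize_hap(others), normalize_hap(haplotype))
  fit_presence_core(data, trait, haplotype, others, spec)
}

#' Diplotype association model with Bonferroni-corrected LSD comparisons
#'
#' Restricted to diplotypes whose frequency on the trait's analyzed subset
#' exceeds `diplotype_min_freq` (default 5\%), fits the trait with
#' diplotype, gender and birth rank as fixed factors and sire as a random
#' intercept (single-level factors, e.g. gender on a males-only carcass
#' subset, are dropped automatically).  The overall p-value is the
#' diplotype term's F test (Satterthwaite).  All `k(k-1)/2` pairwise
#' least-significant-difference comparisons are computed and their
#' p-values multiplied by `k(k-1)/2` (capped at 1) -- a Bonferroni
#' correction over the full family of pairs -- and a compact letter
#' display is assigned by insert-and-absorb so that two diplotypes share
#' no letter exactly when their adjusted p-value is below `alpha`.
#'
#' @param data association data frame, as from [assoc_dataset()].
#' @param trait phenotype column name.
#' @param spec a [model_spec()]; defaults to [default_trait_specs()] for
#'   the trait, with `fixed_factors` overridden to gender + birth rank as
#'   the diplotype series prescribes.
#' @return An object of class `"diplotype_result"`: list with `trait`,
#'   `groups` (diplotype, n, emm, se, letters), `overall_p`, `pairwise`
#'   (g1, g2, p_raw, p_adj), `k`, `note`; or a skip record (`note`
#'   explains) when fewer than two diplotypes pass the filter.
#' @export
fit_diplotype_model <- function(data, trait, spec = NULL) {
  base <- if (is.null(spec)) default_trait_specs()[[trait]] else spec
  if (is.null(base)) {
    stop("no model spec known for trait '", trait, "'", call. = FALSE)
  }
  # diplotype series: diplotype + gender + birth rank fixed, sire random
  dspec <- model_spec(trait, fixed_factors = c("gender", "birth_rank"),
                      covariates = character(),
                      males_only = base$males_only,
                      include_p = base$include_p, alpha = base$alpha,
                      diplotype_min_freq = base$diplotype_min_freq)
  df <- build_model_frame(data, dspec)

  freq <- table(df$diplotype) / nrow(df)
  keep <- names(freq)[freq > dspec$diplotype_min_freq]
  skip <- function(note) {
    structure(list(trait = trait, groups = NULL, overall_p = NA_real_,
                   pairwise = NULL, k = length(keep), note = note),
              class = "diplotype_result")
  }
  if (length(keep) < 2L) {
    return(skip("fewer than two diplotypes pass the frequency filter"))
  }
  df <- df[df$diplotype %in% keep, , drop = FALSE]
  df$diplotype <- factor(df$diplotype, levels = sort(keep))
  # factor levels can degenerate after the diplotype filter
  factors <- attr(df, "factors")
  factors <- factors[vapply(factors, function(v) {
    nlevels(droplevels(df[[v]])) >= 2L
  }, logical(1L))]
  for (v in factors) df[[v]] <- droplevels(df[[v]])
  if (stats::var(df[[trait]]) == 0) {
    return(skip("zero variance in trait"))
  }

  rhs <- c("diplotype", factors)
  f <- stats::as.formula(paste(trait, "~", paste(rhs, collapse = " + ")))
  m <- fit_mixed(f, df)

  if (inherits(m$fit, "lmerModLmerTest")) {
    an <- stats::anova(m$fit)
    overall_p <- an["diplotype", "Pr(>F)"]
  } else {
    an <- stats::drop1(m$fit, test = "F")
    overall_p <- an["diplotype", "Pr(>F)"]
  }

  em <- emm_table(m$fit, "diplotype")
  lev <- as.character(em$diplotype)
  k <- length(lev)
  n_pairs <- k * (k - 1L) / 2L
  pr <- as.data.frame(emmeans::contrast(
    emmeans::emmeans(m$fit, "diplotype", lmer.df = "satterthwaite"),
    method = "pairwise", adjust = "none"))
  idx <- utils::combn(k, 2L)
  pairwise <- data.frame(
    g1 = lev[idx[1L, ]], g2 = lev[idx[2L, ]],
    p_raw = pr$p.value,
    p_adj = pmin(1, pr$p.value * n_pairs),
    stringsAsFactors = FALSE)

  pmat <- matrix(1, k, k, dimnames = list(lev, lev))
  for (r in seq_len(nrow(pairwise))) {
    pmat[pairwise$g1[r], pairwise$g2[r]] <- pairwise$p_adj[r]
    pmat[pairwise$g2[r], pairwise$g1[r]] <- pairwise$p_adj[r]
  }
  letters_out <- letter_display(pmat, alpha = dspec$alpha)

  groups <- data.frame(
    diplotype = lev,
    n = as.integer(table(df$diplotype)[lev]),
    emm = em$emmean, se = em$SE,
    letters = letters_out[lev],
    stringsAsFactors = FALSE)
  rownames(groups) <- NULL

  structure(list(trait = trait, groups = groups, overall_p = overall_p,
                 pairwise = pairwise, k = k,
                 note = if (m$sire_dropped)
                   "sire variance zero: fixed-effects fit" else ""),
            class = "diplotype_result")
}

#' @export
print.diplotype_result <- function(x, ...) {
  cat("Diplotype model for", x$trait, "\n")
  if (is.null(x$groups)) {
    cat("  skipped:", x$note, "\n")
    return(invisible(x))
  }
  cat(sprintf("  overall p = %.3f (%d groups)\n", x$overall_p, x$k))
  for (i in seq_len(nrow(x$groups))) {
    cat(sprintf("  %-24s n=%3d  %8.3f +/- %.3f  %s\n",
                x$groups$diplotype[i], x$groups$n[i], x$groups$emm[i],
                x$groups$se[i], x$groups$letters[i]))
  }
  invisible(x)
}

#' Compact letter display by insert-and-absorb
#'
#' Assigns letters to groups from a symmetric matrix of (adjusted) pairwise
#' p-values so that two groups share no letter exactly when their p-value
#' is below `alpha`.  Implements the insert-and-absorb algorithm: starting
#' from one letter covering all groups, each significant pair splits every
#' letter containing both members into two, and letters wholly contained in
#' another are absorbed.  Column order (and hence lettering) is stabilised
#' by each letter's smallest member, so the display is deterministic.
#'
#' @param pmat symmetric numeric matrix with row/column names naming the
#'   groups.
#' @param alpha significance threshold.
#' @return Named character vector of letter strings, one per group.
#' @export
letter_display <- function(pmat, alpha = 0.05) {
  g <- rownames(pmat)
  k <- length(g)
  cols <- list(seq_len(k))
  sig <- which(pmat < alpha & upper.tri(pmat), arr.ind = TRUE)
  if (nrow(sig)) {
    for (r in seq_len(nrow(sig))) {
      i <- sig[r, 1L]; j <- sig[r, 2L]
      new <- list()
      for (col in cols) {
        if (i %in% col && j %in% col) {
          new <- c(new, list(setdiff(col, i)), list(setdiff(col, j)))
        } else {
          new <- c(new, list(col))
        }
      }
      new <- new[lengths(new) > 0L]
      # absorb duplicates and subsets
      keep <- rep(TRUE, length(new))
      for (a in seq_along(new)) {
        if (!keep[a]) next
        for (b in seq_along(new)) {
          if (a == b || !keep[b]) next
          if (all(new[[a]] %in% new[[b]])) {
            if (length(new[[a]]) < length(new[[b]]) || a > b) {
              keep[a] <- FALSE
              break
            }
          }
        }
      }
      cols <- new[keep]
    }
  }
  cols <- cols[order(vapply(cols, min, 1L))]
  out <- vapply(seq_len(k), function(i) {
    paste(letters[which(vapply(cols, function(cl) i %in% cl, logical(1L)))],
          collapse = ",")
  }, character(1L))
  names(out) <- g
  out
}

#' Choose the litter-size structure term for a trait
#'
#' The same litter-size information can enter a model as birth rank (a
#' factor), birth weight (a covariate) or rearing rank (a factor); this
#' helper fits one candidate at a time on top of the trait's mandatory
#' terms and returns the candidate with the largest partial F statistic.
#' Exact ties are broken by the fixed priority birth rank > birth weight >
#' rearing rank.  Degenerate candidates (single level, zero variance) are
#' skipped; if no candidate reaches `p < 0.05` the selection still returns
#' the largest-F candidate, flagged.
#'
#' @param data association data frame.
#' @param trait phenotype column name.
#' @param mandatory character vector of terms always in the model (e.g.
#'   `"gender"`).
#' @return List with `term` (chosen candidate or `NA`), `table` (candidate,
#'   F, p) and `note`.
#' @export
select_structure_term <- function(data, trait, mandatory = "gender") {
  candidates <- c("birth_rank", "birth_weight", "rearing_rank")
  ok <- is.finite(data[[trait]])
  for (v in c(mandatory, candidates)) {
    if (v %in% names(data)) ok <- ok & !is.na(data[[v]])
  }
  df <- data[ok, , drop = FALSE]
  for (v in intersect(c(mandatory, "birth_rank", "rearing_rank"), names(df))) {
    df[[v]] <- factor(df[[v]])
  }

  rows <- list()
  for (cand in candidates) {
    if (!cand %in% names(df)) next
    degenerate <- if (is.factor(df[[cand]])) {
      nlevels(droplevels(df[[cand]])) < 2L
    } else {
      stats::var(df[[cand]]) == 0
    }
    if (degenerate) next
    f <- stats::as.formula(paste(trait, "~",
                                 paste(c(mandatory, cand), collapse = " + ")))
    an <- stats::anova(stats::lm(f, data = df))
    rows[[cand]] <- data.frame(candidate = cand,
                               F = an[cand, "F value"],
                               p = an[cand, "Pr(>F)"],
                               stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(list(term = NA_character_, table = NULL,
                note = "all candidates degenerate"))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  # largest F wins; candidates are evaluated in priority order, so the
  # strict ">" comparison resolves exact ties by that priority
  best <- tab$candidate[1L]
  for (i in seq_len(nrow(tab))) {
    if (tab$F[i] > tab$F[tab$candidate == best] + 1e-8) {
      best <- tab$candidate[i]
    }
  }
  note <- if (all(tab$p >= 0.05)) "no candidate p < 0.05" else ""
  list(term = best, table = tab, note = note)
}

#' Growth-rate effect expressed per day and cumulatively
#'
#' Converts the estimated marginal means of the absent and present groups
#' into a per-day growth difference (g/day) and the cumulative weight
#' difference over a given number of days (g), e.g. from birth to weaning.
#'
#' @param emm_absent,emm_present estimated marginal means, g/day.
#' @param days number of days over which to accumulate (positive).
#' @return List with `per_day` (g/day) and `cumulative` (g).
#' @examples
#' derived_growth_effect(275.9, 268.2, 100)  # 7.7 g/day, 770 g
#' @export
derived_growth_effect <- function(emm_absent, emm_present, days) {
  if (any(days <= 0)) stop("days must be positive", call. = FALSE)
  per_day <- emm_absent - emm_present
  list(per_day = per_day, cumulative = per_day * days)
}

#' Lean-meat mass equivalent of a yield difference
#'
#' Converts a lean-meat yield difference (percentage points of hot carcass
#' weight) into grams of lean meat for a carcass of given weight, rounded
#' to the nearest gram.
#'
#' @param yield_diff yield difference, percentage points.
#' @param carcass_weight hot carcass weight, kg (positive).
#' @return Lean-meat difference in grams (integer-valued).
#' @examples
#' derived_meat_effect(0.71, 18)  # 128 g
#' @export
derived_meat_effect <- function(yield_diff, carcass_weight) {
  if (any(carcass_weight <= 0)) {
    stop("carcass weight must be positive", call. = FALSE)
  }
  round(carcass_weight * 1000 * yield_diff / 100)
}

#' Run the single- and adjusted-haplotype series over several traits
#'
#' For each trait, fits the single presence/absence model for every
#' haplotype in `haplotypes` (default: haplotypes with frequency above
#' `min_hap_freq` among resolved animals, mirroring the common-haplotype
#' convention), then re-fits each haplotype whose single-model p fell
#' below the inclusion threshold with the other sub-threshold haplotypes
#' co-fitted.
#'
#' @param data association data frame, as from [assoc_dataset()].
#' @param traits character vector of phenotype column names.
#' @param haplotypes haplotypes to assess; `NULL` selects by frequency.
#' @param specs named list of [model_spec()] objects (default
#'   [default_trait_specs()]).
#' @param min_hap_freq frequency threshold for automatic haplotype
#'   selection (default 0.05).
#' @return List with `single` and `adjusted` data frames of
#'   `"assoc_result"` rows.
#' @export
run_haplotype_series <- function(data, traits, haplotypes = NULL,
                                 specs = default_trait_specs(),
                                 min_hap_freq = 0.05) {
  if (is.null(haplotypes)) {
    ft <- estimate_frequencies(data.frame(resolved = data$diplotype))
    haplotypes <- ft$haplotypes$haplotype[ft$haplotypes$frequency > min_hap_freq]
  }
  single <- list()
  adjusted <- list()
  for (tr in traits) {
    spec <- specs[[tr]]
    srows <- lapply(haplotypes, function(h) {
      fit_presence_model(data, tr, h, spec)
    })
    srows <- do.call(rbind, srows)
    single[[tr]] <- srows
    sub <- srows$haplotype[!is.na(srows$p_value) &
                             srows$p_value < spec$include_p]
    for (h in sub) {
      others <- setdiff(sub, h)
      if (!length(others)) next
      adjusted[[paste(tr, h)]] <- fit_adjusted_model(data, tr, h, others, spec)
    }
  }
  list(single = do.call(rbind, c(single, list(make.row.names = FALSE))),
       adjusted = if (length(adjusted)) {
         do.call(rbind, c(adjusted, list(make.row.names = FALSE)))
       } else {
         NULL
       })
}

#' Run the diplotype series over several traits
#'
#' @inheritParams run_haplotype_series
#' @return Named list of `"diplotype_result"` objects, one per trait.
#' @export
run_diplotype_series <- function(data, traits,
                                 specs = default_trait_specs()) {
  out <- lapply(traits, function(tr) {
    fit_diplotype_model(data, tr, specs[[tr]])
  })
  names(out) <- traits
  out
}
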