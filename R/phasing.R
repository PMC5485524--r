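#' Enumerate the diplotypes compatible with a pair of region genotypes
#'
#' Given the unphased genotypes observed at the two regions, returns every
#' two-locus diplotype whose region-wise collapse reproduces them.  An
#' animal homozygous at either region has a single compatible diplotype and
#' can be phased directly from co-inheritance; an animal heterozygous at
#' both regions has exactly two, and needs its sire's diplotype to choose
#' between them.
#'
#' @param g_prom unphased promoter--exon 1 genotype, `"A1/B1"` form.
#' @param g_coding unphased intron 2--exon 3 genotype, `"A3/B3"` form.
#' @return Sorted character vector of candidate diplotype identifiers
#'   (length 1 or 2).
#' @examples
#' enumerate_candidate_diplotypes("A1/A1", "A3/B3")  # direct: one candidate
#' enumerate_candidate_diplotypes("A1/B1", "A3/C3")  # two candidates
#' @export
enumerate_candidate_diplotypes <- function(g_prom, g_coding) {
  p <- strsplit(g_prom, "/", fixed = TRUE)[[1L]]
  k <- strsplit(g_coding, "/", fixed = TRUE)[[1L]]
  if (length(p) != 2L || length(k) != 2L) {
    stop("genotypes must be 'label/label' pairs", call. = FALSE)
  }
  cis <- diplotype(paste0(p[1L], "-", k[1L]), paste0(p[2L], "-", k[2L]))
  trans <- diplotype(paste0(p[1L], "-", k[2L]), paste0(p[2L], "-", k[1L]))
  sort(unique(c(cis, trans)))
}

# does diplotype `dip` share at least one haplotype with the sire pair?
shares_sire_hap <- function(dip, sire_haps) {
  hm <- dip_haps(dip)
  hm[, "hap1"] %in% sire_haps | hm[, "hap2"] %in% sire_haps
}

#' Reconstruct a sire's diplotype from its progeny
#'
#' Each progeny inherits exactly one of its sire's two haplotypes, so
#' across a half-sib family roughly half the progeny carry each sire
#' haplotype.  The reconstruction enumerates candidate sire diplotypes
#' (from the sire's own region genotypes when supplied, otherwise all
#' unordered pairs of haplotypes observed in the family), discards
#' candidates incompatible with any progeny, and scores the survivors by
#' support: the number of directly phased progeny (unique candidate set)
#' that carry at least one of the candidate's haplotypes.  The unique
#' maximal-support consistent candidate is chosen; ties and empty
#' consistent sets are surfaced as ambiguity, never broken arbitrarily.
#'
#' A progeny incompatible with every candidate sire diplotype (e.g. a
#' genotyping error) is flagged inconsistent and set aside so that it does
#' not veto the reconstruction for its siblings.
#'
#' @param progeny_candidates list of candidate-diplotype character vectors,
#'   one per progeny, as from [enumerate_candidate_diplotypes()].
#' @param sire_genotypes optional list with elements `prom` and `coding`
#'   giving the sire's own unphased region genotypes.
#' @param sire_id optional identifier carried through to the result.
#' @return An object of class `"sire_estimate"`: list with `sire_id`,
#'   `candidates` (data frame: diplotype, support, consistent), `chosen`
#'   (diplotype or `NA`), `ambiguous` flag, and `inconsistent` (indices of
#'   progeny incompatible with every candidate).
#' @export
reconstruct_sire_diplotype <- function(progeny_candidates,
                                       sire_genotypes = NULL,
                                       sire_id = NA_character_) {
  if (length(progeny_candidates) < 1L) {
    stop("at least one progeny is required", call. = FALSE)
  }

  if (!is.null(sire_genotypes)) {
    cand <- enumerate_candidate_diplotypes(sire_genotypes$prom,
                                           sire_genotypes$coding)
  } else {
    haps <- sort(unique(unlist(lapply(progeny_candidates, function(d) {
      as.vector(dip_haps(d))
    }))))
    idx <- which(upper.tri(matrix(0, length(haps), length(haps)),
                           diag = TRUE), arr.ind = TRUE)
    cand <- sort(diplotype(haps[idx[, 1L]], haps[idx[, 2L]]))
  }

  compat <- function(prog_cands, sire_dip) {
    any(shares_sire_hap(prog_cands, dip_haps(sire_dip)[1L, ]))
  }

  # progeny compatible with no candidate at all: flag, don't let them veto
  ok_any <- vapply(progeny_candidates, function(pc) {
    any(vapply(cand, function(sd) compat(pc, sd), logical(1L)))
  }, logical(1L))
  inconsistent <- which(!ok_any)
  usable <- progeny_candidates[ok_any]

  consistent <- vapply(cand, function(sd) {
    all(vapply(usable, function(pc) compat(pc, sd), logical(1L)))
  }, logical(1L))

  direct <- progeny_candidates[lengths(progeny_candidates) == 1L]
  support <- vapply(cand, function(sd) {
    if (!length(direct)) return(0L)
    sum(vapply(direct, function(d) compat(d, sd), logical(1L)))
  }, integer(1L))

  chosen <- NA_character_
  ambiguous <- TRUE
  if (any(consistent)) {
    cc <- cand[consistent]
    ss <- support[consistent]
    best <- cc[ss == max(ss)]
    if (length(best) == 1L) {
      chosen <- best
      ambiguous <- FALSE
    }
  }

  structure(list(
    sire_id = sire_id,
    candidates = data.frame(diplotype = cand, support = support,
                            consistent = consistent,
                            stringsAsFactors = FALSE),
    chosen = chosen, ambiguous = ambiguous,
    inconsistent = inconsistent
  ), class = "sire_estimate")
}

#' @export
print.sire_estimate <- function(x, ...) {
  cat("Sire", x$sire_id, "->",
      if (is.na(x$chosen)) "ambiguous" else x$chosen, "\n")
  invisible(x)
}

#' Resolve one progeny's diplotype against its sire estimate
#'
#' A progeny with a single candidate diplotype is phased directly.  A
#' double heterozygote keeps the candidates that share at least one
#' haplotype with the chosen sire diplotype: exactly one survivor phases it
#' (`sire_informed`); no survivor means a Mendelian conflict
#' (`inconsistent`); two survivors, or an ambiguous sire, leave it
#' `unresolved` -- it is excluded downstream rather than imputed.
#'
#' @param candidates candidate diplotypes for the progeny (length 1 or 2).
#' @param sire a `"sire_estimate"`.
#' @return List with `candidates`, `resolved` (diplotype or `NA`) and
#'   `method` (`"direct"`, `"sire_informed"`, `"unresolved"` or
#'   `"inconsistent"`).
#' @export
resolve_progeny <- function(candidates, sire) {
  if (!length(candidates) %in% c(1L, 2L)) {
    stop("candidate set must have size 1 or 2", call. = FALSE)
  }
  if (length(candidates) == 1L) {
    return(list(candidates = candidates, resolved = candidates,
                method = "direct"))
  }
  if (is.na(sire$chosen)) {
    return(list(candidates = candidates, resolved = NA_character_,
                method = "unresolved"))
  }
  sire_haps <- dip_haps(sire$chosen)[1L, ]
  keep <- candidates[shares_sire_hap(candidates, sire_haps)]
  if (length(keep) == 1L) {
    list(candidates = candidates, resolved = keep, method = "sire_informed")
  } else if (length(keep) == 0L) {
    list(candidates = candidates, resolved = NA_character_,
         method = "inconsistent")
  } else {
    list(candidates = candidates, resolved = NA_character_,
         method = "unresolved")
  }
}

#' Phase a whole half-sib cohort
#'
#' Two passes over the cohort.  Pass 1 enumerates candidate diplotypes for
#' every animal and reconstructs every sire's diplotype from its half-sib
#' family (using the sire's own genotypes when a sire row carrying them is
#' present).  Pass 2 resolves the double heterozygotes against their sire
#' estimates.  Unresolved and inconsistent progeny are retained with a null
#' diplotype so that downstream stages can drop them per trait.
#'
#' Rows whose `animal_id` appears in the `sire_id` column are treated as
#' sire rows; all other rows are progeny and must carry a sire id.
#'
#' @param records animal-record data frame (the `records` component of an
#'   `"animal_table"`).
#' @return An object of class `"phasing_result"`: list with
#'   \describe{
#'     \item{outcomes}{data frame, one row per progeny: `animal_id`,
#'       `sire_id`, `candidates` (pipe-separated), `resolved`, `method`;}
#'     \item{sires}{named list of `"sire_estimate"` objects.}
#'   }
#' @export
phase_cohort <- function(records) {
  sire_ids <- sort(unique(records$sire_id[!is.na(records$sire_id)]))
  is_sire_row <- records$animal_id %in% sire_ids
  progeny <- records[!is_sire_row, , drop = FALSE]

  orphans <- progeny$animal_id[is.na(progeny$sire_id)]
  if (length(orphans)) {
    stop("integrity error: unknown sire for progeny ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }

  usable <- !is.na(progeny$genotype_prom) & !is.na(progeny$genotype_coding)
  cand_list <- vector("list", nrow(progeny))
  for (i in which(usable)) {
    cand_list[[i]] <- enumerate_candidate_diplotypes(
      progeny$genotype_prom[i], progeny$genotype_coding[i])
  }

  sires <- list()
  for (sid in sire_ids) {
    fam <- which(progeny$sire_id == sid & usable)
    if (!length(fam)) next
    sire_row <- records[is_sire_row & records$animal_id == sid, , drop = FALSE]
    sire_gt <- NULL
    if (nrow(sire_row) == 1L && !is.na(sire_row$genotype_prom) &&
        !is.na(sire_row$genotype_coding)) {
      sire_gt <- list(prom = sire_row$genotype_prom,
                      coding = sire_row$genotype_coding)
    }
    est <- reconstruct_sire_diplotype(cand_list[fam], sire_genotypes = sire_gt,
                                      sire_id = sid)
    est$inconsistent <- progeny$animal_id[fam][est$inconsistent]
    sires[[sid]] <- est
  }

  n <- nrow(progeny)
  resolved <- rep(NA_character_, n)
  method <- rep("unresolved", n)
  for (i in seq_len(n)) {
    if (!usable[i]) next
    sid <- progeny$sire_id[i]
    est <- sires[[sid]]
    if (progeny$animal_id[i] %in% est$inconsistent) {
      method[i] <- "inconsistent"
      next
    }
    r <- resolve_progeny(cand_list[[i]], est)
    resolved[i] <- r$resolved
    method[i] <- r$method
  }

  outcomes <- data.frame(
    animal_id = progeny$animal_id,
    sire_id = progeny$sire_id,
    candidates = vapply(cand_list, function(x) {
      if (is.null(x)) "" else paste(x, collapse = "|")
    }, character(1L)),
    resolved = resolved,
    method = method,
    stringsAsFactors = FALSE)

  structure(list(outcomes = outcomes, sires = sires),
            class = "phasing_result")
}

#' @export
print.phasing_result <- function(x, ...) {
  tab <- table(factor(x$outcomes$method,
                      levels = c("direct", "sire_informed", "unresolved",
                                 "inconsistent")))
  cat("Phasing of", nrow(x$outcomes), "progeny across",
      length(x$sires), "sires\n")
  for (m in names(tab)) cat(sprintf("  %-14s %d\n", m, tab[[m]]))
  invisible(x)
}

#' Haplotype and diplotype frequencies by chromosome counting
#'
#' Counts chromosomes over the resolved animals only: each resolved animal
#' contributes two chromosomes (a homozygote contributes two copies of the
#' same haplotype).  Diplotype frequencies are proportions of resolved
#' animals.  Both tables are sorted by descending frequency (identifier as
#' tie-break) so output is deterministic.
#'
#' @param outcomes the `outcomes` data frame of a `"phasing_result"` (or
#'   any frame with a `resolved` column).
#' @return An object of class `"hap_freq"`: list with `haplotypes` and
#'   `diplotypes` data frames (`count`, `frequency`), `n_animals` and
#'   `n_chromosomes`.
#' @examples
#' out <- data.frame(resolved = c("A1-A3/A1-A3", "A1-A3/B1-A3"))
#' estimate_frequencies(out)
#' @export
estimate_frequencies <- function(outcomes) {
  res <- outcomes$resolved[!is.na(outcomes$resolved)]
  if (!length(res)) {
    stop("no resolved animals: frequencies are undefined", call. = FALSE)
  }
  hm <- dip_haps(res)
  hcount <- table(c(hm[, "hap1"], hm[, "hap2"]))
  htab <- data.frame(haplotype = names(hcount),
                     count = as.integer(hcount),
                     frequency = as.numeric(hcount) / (2 * length(res)),
                     stringsAsFactors = FALSE)
  htab <- htab[order(-htab$frequency, htab$haplotype), , drop = FALSE]
  rownames(htab) <- NULL

  dcount <- table(res)
  dtab <- data.frame(diplotype = names(dcount),
                     count = as.integer(dcount),
                     frequency = as.numeric(dcount) / length(res),
                     stringsAsFactors = FALSE)
  dtab <- dtab[order(-dtab$frequency, dtab$diplotype), , drop = FALSE]
  rownames(dtab) <- NULL

  structure(list(haplotypes = htab, diplotypes = dtab,
                 n_animals = length(res), n_chromosomes = 2L * length(res)),
            class = "hap_freq")
}

#' @export
print.hap_freq <- function(x, ...) {
  cat("Haplotype frequencies (", x$n_chromosomes, " chromosomes from ",
      x$n_animals, " resolved animals)\n", sep = "")
  pct <- round_percent_total(x$haplotypes$frequency)
  for (i in seq_len(nrow(x$haplotypes))) {
    cat(sprintf("  %-8s %5d  %6.2f%%\n", x$haplotypes$haplotype[i],
                x$haplotypes$count[i], pct[i]))
  }
  invisible(x)
}

# Round a frequency vector to percentages with 2 decimals that sum to
# exactly 100.00 (largest-remainder allocation of the rounding residue).
round_percent_total <- function(freq, digits = 2L) {
  scale <- 10^digits
  raw <- freq / sum(freq) * 100 * scale
  fl <- floor(raw)
  short <- round(100 * scale - sum(fl))
  rem <- raw - fl
  add <- rep(0, length(fl))
  if (short > 0) {
    add[order(-rem, seq_along(rem))[seq_len(short)]] <- 1
  }
  (fl + add) / scale
}
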