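#' Read and validate a run configuration
#'
#' Run configurations are YAML files with (all optional, defaults shown):
#' ```yaml
#' input: cohort.tsv          # animal table for phase/associate
#' out_dir: results           # where stage outputs are written
#' traits: [growth_rate, vgr] # traits for the association stage
#' alpha: 0.05
#' include_p: 0.20
#' diplotype_min_freq: 0.05
#' simulate:                  # overrides for the simulate stage
#'   seed: 1
#'   n_sires: 17
#'   n_progeny: 1185
#' ```
#'
#' @param path YAML file path, or a list already in that shape.
#' @return A validated list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  defaults <- list(input = NULL, out_dir = ".", traits = c("growth_rate"),
                   alpha = 0.05, include_p = 0.20, diplotype_min_freq = 0.05,
                   simulate = list(), verbose = TRUE)
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  for (th in c("alpha", "include_p", "diplotype_min_freq")) {
    v <- cfg[[th]]
    if (!is.numeric(v) || v <= 0 || v >= 1) {
      stop("config error: ", th, " must lie in (0, 1)", call. = FALSE)
    }
  }
  known <- names(default_trait_specs())
  bad <- setdiff(cfg$traits, known)
  if (length(bad)) {
    stop("config error: unknown trait(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

run_log <- function(lines, out_dir, stage) {
  path <- file.path(out_dir, paste0(stage, ".log"))
  writeLines(lines, path)
  invisible(path)
}

fmt_num <- function(x, digits) {
  digits <- rep_len(digits, length(x))
  vapply(seq_along(x), function(i) {
    if (is.na(x[i])) "" else formatC(x[i], format = "f", digits = digits[i])
  }, character(1L))
}

# decimal rendering conventions: weights 2 dp, growth rate 1 dp, yields and
# fat depth 2 dp, p-values 3 dp
trait_digits <- function(trait) {
  if (trait %in% c("growth_rate")) 1L else 2L
}

#' Simulate a cohort and write it to disk
#'
#' Runs the synthetic generator with the configuration's `simulate`
#' parameters and writes the animal table (`cohort.tsv`), the latent truth
#' table (`truth.tsv`, clearly synthetic) and a log.  A seed is mandatory,
#' either in the configuration or via `seed`.
#'
#' @param config a [read_run_config()] result, a path to one, or `NULL`
#'   for defaults.
#' @param seed optional seed overriding the configuration.
#' @return Invisibly, list of written paths.
#' @export
cmd_simulate <- function(config = NULL, seed = NULL) {
  cfg <- if (is.null(config)) read_run_config(list()) else
    if (inherits(config, "run_config")) config else read_run_config(config)
  sim_args <- cfg$simulate
  if (!is.null(seed)) sim_args$seed <- seed
  if (is.null(sim_args$seed)) {
    stop("config error: simulate requires a seed", call. = FALSE)
  }
  sc <- do.call(sim_config, sim_args)
  cohort <- generate_cohort(sc)

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort_path <- file.path(cfg$out_dir, "cohort.tsv")
  truth_path <- file.path(cfg$out_dir, "truth.tsv")
  write_animal_table(cohort$records, cohort_path)
  write_animal_table(cohort$truth, truth_path)
  run_log(c(sprintf("simulate: seed=%d n_sires=%d n_progeny=%d",
                    sc$seed, sc$n_sires, sc$n_progeny),
            sprintf("simulate: wrote %d records (%d sire rows)",
                    nrow(cohort$records),
                    nrow(cohort$records) - nrow(cohort$truth))),
          cfg$out_dir, "simulate")
  invisible(list(cohort = cohort_path, truth = truth_path))
}

#' Phase a cohort file and write the phasing tables
#'
#' Reads the animal table named by the configuration's `input` (default:
#' `cohort.tsv` in `out_dir`), phases it, and writes `phasing.tsv` (per
#' progeny: candidates, resolved diplotype, method), `sire_estimates.tsv`,
#' and the haplotype/diplotype frequency tables (`hap_freq.tsv`,
#' `dip_freq.tsv`) whose rendered percentages sum to exactly 100.00.
#'
#' @param config a [read_run_config()] result or path.
#' @return Invisibly, list of written paths.
#' @export
cmd_phase <- function(config = NULL) {
  cfg <- if (is.null(config)) read_run_config(list()) else
    if (inherits(config, "run_config")) config else read_run_config(config)
  input <- if (!is.null(cfg$input)) cfg$input else
    file.path(cfg$out_dir, "cohort.tsv")
  tab <- read_animal_table(input)
  ph <- phase_cohort(tab$records)
  freq <- estimate_frequencies(ph$outcomes)

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    phasing = file.path(cfg$out_dir, "phasing.tsv"),
    sires = file.path(cfg$out_dir, "sire_estimates.tsv"),
    hap_freq = file.path(cfg$out_dir, "hap_freq.tsv"),
    dip_freq = file.path(cfg$out_dir, "dip_freq.tsv"))

  utils::write.table(ph$outcomes, paths$phasing, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  sire_tab <- do.call(rbind, lapply(ph$sires, function(s) {
    data.frame(sire_id = s$sire_id,
               chosen = ifelse(is.na(s$chosen), "", s$chosen),
               ambiguous = s$ambiguous,
               n_candidates = nrow(s$candidates),
               n_inconsistent_progeny = length(s$inconsistent),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(sire_tab, paths$sires, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  write_freq <- function(tab, idcol, path) {
    out <- data.frame(tab[[idcol]], count = tab$count,
                      percent = fmt_num(round_percent_total(tab$frequency), 2))
    names(out)[1L] <- idcol
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_freq(freq$haplotypes, "haplotype", paths$hap_freq)
  write_freq(freq$diplotypes, "diplotype", paths$dip_freq)

  meth <- table(factor(ph$outcomes$method,
                       levels = c("direct", "sire_informed", "unresolved",
                                  "inconsistent")))
  run_log(c(sprintf("phase: input=%s progeny=%d", input, nrow(ph$outcomes)),
            sprintf("phase: %s=%d", names(meth), as.integer(meth)),
            sprintf("phase: excluded downstream (unresolved+inconsistent)=%d",
                    sum(is.na(ph$outcomes$resolved)))),
          cfg$out_dir, "phase")
  invisible(paths)
}

render_single_table <- function(res, alpha) {
  if (is.null(res) || !nrow(res)) return(NULL)
  digits <- vapply(res$trait, trait_digits, 1L)
  data.frame(
    trait = res$trait,
    haplotype = res$haplotype,
    others_in_model = ifelse(res$others == "", "-", res$others),
    mean_se_absent = paste0(fmt_num(res$emm_absent, digits), " ± ",
                            fmt_num(res$se_absent, digits)),
    n_absent = res$n_absent,
    mean_se_present = paste0(fmt_num(res$emm_present, digits), " ± ",
                             fmt_num(res$se_present, digits)),
    n_present = res$n_present,
    p_value = fmt_num(res$p_value, 3),
    signif = ifelse(is.na(res$p_value), "",
                    classify_significance(pmin(pmax(res$p_value, 0), 1),
                                          alpha = alpha)),
    stringsAsFactors = FALSE)
}

render_diplotype_table <- function(dres) {
  rows <- list()
  for (tr in names(dres)) {
    r <- dres[[tr]]
    if (is.null(r$groups)) next
    d <- trait_digits(tr)
    rows[[tr]] <- data.frame(
      trait = tr,
      diplotype = r$groups$diplotype,
      n = r$groups$n,
      mean_se = paste0(fmt_num(r$groups$emm, d), " ± ",
                       fmt_num(r$groups$se, d)),
      letters = r$groups$letters,
      overall_p = fmt_num(r$overall_p, 3),
      signif = classify_significance(min(max(r$overall_p, 0), 1)),
      stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else NULL
}

#' Run the three association series and write the result tables
#'
#' Reads the cohort and its phasing (running [cmd_phase()] outputs if
#' present, otherwise phasing in-memory), then fits the single-haplotype,
#' adjusted and diplotype series over the configured traits.  Writes
#' rendered tables (`table_single.tsv`, `table_adjusted.tsv`,
#' `table_diplotype.tsv`) with the package's decimal conventions and
#' significance classification, plus a machine-readable long results file
#' (`results_long.tsv`).
#'
#' @param config a [read_run_config()] result or path.
#' @return Invisibly, list of written paths.
#' @export
cmd_associate <- function(config = NULL) {
  cfg <- if (is.null(config)) read_run_config(list()) else
    if (inherits(config, "run_config")) config else read_run_config(config)
  input <- if (!is.null(cfg$input)) cfg$input else
    file.path(cfg$out_dir, "cohort.tsv")
  tab <- read_animal_table(input)
  ph <- phase_cohort(tab$records)
  data <- assoc_dataset(tab$records, ph)

  specs <- default_trait_specs()
  for (tr in names(specs)) {
    specs[[tr]]$alpha <- cfg$alpha
    specs[[tr]]$include_p <- cfg$include_p
    specs[[tr]]$diplotype_min_freq <- cfg$diplotype_min_freq
  }

  series <- run_haplotype_series(data, cfg$traits, specs = specs)
  dseries <- run_diplotype_series(data, cfg$traits, specs = specs)

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(single = file.path(cfg$out_dir, "table_single.tsv"),
                adjusted = file.path(cfg$out_dir, "table_adjusted.tsv"),
                diplotype = file.path(cfg$out_dir, "table_diplotype.tsv"),
                long = file.path(cfg$out_dir, "results_long.tsv"))

  wt <- function(x, path) {
    if (is.null(x)) x <- data.frame(note = "no rows")
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  wt(render_single_table(series$single, cfg$alpha), paths$single)
  wt(render_single_table(series$adjusted, cfg$alpha), paths$adjusted)
  wt(render_diplotype_table(dseries), paths$diplotype)

  long <- rbind(series$single,
                if (!is.null(series$adjusted)) series$adjusted)
  wt(long, paths$long)

  n_excl <- sum(is.na(data$diplotype[!is.na(data$sire_id)]))
  run_log(c(sprintf("associate: input=%s traits=%s", input,
                    paste(cfg$traits, collapse = ",")),
            sprintf("associate: progeny with null diplotype dropped=%d",
                    n_excl),
            sprintf("associate: single rows=%d adjusted rows=%d",
                    if (is.null(series$single)) 0L else nrow(series$single),
                    if (is.null(series$adjusted)) 0L
                    else nrow(series$adjusted))),
          cfg$out_dir, "associate")
  invisible(paths)
}

#' Summarize a results directory on the console
#'
#' Reads the frequency and association tables written by [cmd_phase()] and
#' [cmd_associate()] from a directory and prints a compact plain-text
#' summary.
#'
#' @param in_dir directory holding stage outputs.
#' @return Invisibly, the lines printed.
#' @export
cmd_report <- function(in_dir = ".") {
  lines <- character()
  say <- function(...) lines <<- c(lines, sprintf(...))
  hf <- file.path(in_dir, "hap_freq.tsv")
  if (file.exists(hf)) {
    tab <- utils::read.delim(hf, colClasses = "character")
    say("Haplotype frequencies:")
    for (i in seq_len(nrow(tab))) {
      say("  %-8s %6s%%", tab$haplotype[i], tab$percent[i])
    }
  }
  ts <- file.path(in_dir, "table_single.tsv")
  if (file.exists(ts)) {
    tab <- utils::read.delim(ts, colClasses = "character",
                             check.names = FALSE)
    if ("signif" %in% names(tab)) {
      hits <- tab[tab$signif %in% c("significant", "trend"), , drop = FALSE]
      say("Single-haplotype associations (significant or trend): %d",
          nrow(hits))
      for (i in seq_len(nrow(hits))) {
        say("  %s ~ %s: p=%s (%s)", hits$trait[i], hits$haplotype[i],
            hits$p_value[i], hits$signif[i])
      }
    }
  }
  if (!length(lines)) say("no results found in %s", in_dir)
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
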