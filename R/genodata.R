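#' Default column map for the animal table
#'
#' Maps the internal field names onto the column names expected in the
#' delimited input file.  Supplying a modified copy to
#' [read_animal_table()] adapts the reader to files with different
#' headers.  Fields set to `NA` are treated as absent from the file.
#'
#' @return Named character vector: internal field -> file column name.
#' @export
default_columns <- function() {
  fields <- c("animal_id", "sire_id", "gender", "birth_rank", "rearing_rank",
              "age_weaning", "age_slaughter",
              "genotype_prom", "genotype_coding",
              "birth_weight", "tailing_weight", "weaning_weight",
              "growth_rate", "hot_carcass_weight", "vgr",
              "leg_yield", "loin_yield", "shoulder_yield",
              "total_yield", "prop_leg", "prop_loin", "prop_shoulder")
  stats::setNames(fields, fields)
}

MANDATORY_FIELDS <- c("animal_id", "sire_id", "gender", "birth_rank",
                      "rearing_rank", "genotype_prom", "genotype_coding")
CARCASS_FIELDS <- c("hot_carcass_weight", "vgr", "leg_yield", "loin_yield",
                    "shoulder_yield", "total_yield", "prop_leg", "prop_loin",
                    "prop_shoulder")
RANK_LEVELS <- c("single", "twin", "triplet")
GENDER_LEVELS <- c("male", "female")

#' Read an animal table from delimited text
#'
#' Reads one animal per row from a comma- or tab-delimited UTF-8 file (the
#' delimiter is auto-detected from the header line), validates every field,
#' and returns the clean records together with a validation report.  Rows
#' failing hard validation (unparseable genotype, unknown variant label,
#' malformed gender or rank) are excluded and listed in the report; softer
#' issues (carcass values on a female, disagreement between an explicit
#' derived column and its recomputation) are repaired and reported without
#' excluding the row.
#'
#' Pre-weaning growth rate (g/day) is recomputed from birth weight, weaning
#' weight and age at weaning whenever those are present and no explicit
#' growth-rate column exists; when an explicit column is present it wins and
#' the skipped recomputation is logged.  Total lean-meat yield and the three
#' proportion yields are always derived from the leg/loin/shoulder yields
#' via [derive_composition()]; explicit columns that disagree beyond 1e-6
#' are reported and overwritten.
#'
#' @param path path to the delimited text file.
#' @param col_map column map as from [default_columns()].
#' @param registry a [variant_registry()].
#' @return A list of class `"animal_table"` with components:
#'   \describe{
#'     \item{records}{data frame, one row per accepted animal;}
#'     \item{report}{data frame with columns `animal_id`, `field`,
#'       `message`, `action` (`"excluded"`, `"repaired"` or `"info"`).}
#'   }
#' @export
read_animal_table <- function(path, col_map = default_columns(),
                              registry = variant_registry()) {
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(), quote = "\"",
                           comment.char = "", fileEncoding = "UTF-8")

  missing_cols <- setdiff(col_map[MANDATORY_FIELDS], names(raw))
  if (length(missing_cols)) {
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  get_col <- function(field) {
    cn <- col_map[[field]]
    if (is.null(cn) || is.na(cn) || !cn %in% names(raw)) {
      rep(NA_character_, nrow(raw))
    } else {
      trimws(raw[[cn]])
    }
  }

  ids <- get_col("animal_id")
  if (anyDuplicated(ids)) {
    stop("integrity error: duplicate animal id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }

  n <- nrow(raw)
  report <- list()
  note <- function(id, field, message, action) {
    report[[length(report) + 1L]] <<- data.frame(
      animal_id = id, field = field, message = message, action = action,
      stringsAsFactors = FALSE)
  }

  num_field <- function(field) {
    x <- get_col(field)
    out <- suppressWarnings(as.numeric(x))
    bad <- which(nzchar(x) & !is.na(x) & (is.na(out) | !is.finite(out)))
    for (i in bad) {
      note(ids[i], field, paste0("non-numeric value '", x[i], "' set to NA"),
           "repaired")
      out[i] <- NA_real_
    }
    out[!nzchar(x)] <- NA_real_
    out
  }

  enum_field <- function(field, levels) {
    x <- tolower(get_col(field))
    x[!nzchar(x)] <- NA_character_
    x
  }

  gender <- enum_field("gender", GENDER_LEVELS)
  birth_rank <- enum_field("birth_rank", RANK_LEVELS)
  rearing_rank <- enum_field("rearing_rank", RANK_LEVELS)

  gp_raw <- get_col("genotype_prom")
  gc_raw <- get_col("genotype_coding")
  gp <- gc <- rep(NA_character_, n)
  exclude <- rep(FALSE, n)

  for (i in seq_len(n)) {
    pg <- parse_genotype(gp_raw[i], "PROM_EX1", registry)
    if (!is.null(pg$error)) {
      note(ids[i], "genotype_prom", pg$error, "excluded"); exclude[i] <- TRUE
    }
    cg <- parse_genotype(gc_raw[i], "INT2_EX3", registry)
    if (!is.null(cg$error)) {
      note(ids[i], "genotype_coding", cg$error, "excluded"); exclude[i] <- TRUE
    }
    gp[i] <- pg$value
    gc[i] <- cg$value
    if (!is.na(gender[i]) && !gender[i] %in% GENDER_LEVELS) {
      note(ids[i], "gender", paste0("malformed gender '", gender[i], "'"),
           "excluded"); exclude[i] <- TRUE
    }
    for (f in c("birth_rank", "rearing_rank")) {
      v <- if (f == "birth_rank") birth_rank[i] else rearing_rank[i]
      if (!is.na(v) && !v %in% RANK_LEVELS) {
        note(ids[i], f, paste0("rank '", v, "' not in single/twin/triplet"),
             "excluded"); exclude[i] <- TRUE
      }
    }
  }

  sire_id <- get_col("sire_id")
  sire_id[!nzchar(sire_id)] <- NA_character_

  rec <- data.frame(
    animal_id = ids, sire_id = sire_id, gender = gender,
    birth_rank = birth_rank, rearing_rank = rearing_rank,
    age_weaning = num_field("age_weaning"),
    age_slaughter = num_field("age_slaughter"),
    genotype_prom = gp, genotype_coding = gc,
    birth_weight = num_field("birth_weight"),
    tailing_weight = num_field("tailing_weight"),
    weaning_weight = num_field("weaning_weight"),
    growth_rate = num_field("growth_rate"),
    hot_carcass_weight = num_field("hot_carcass_weight"),
    vgr = num_field("vgr"),
    leg_yield = num_field("leg_yield"),
    loin_yield = num_field("loin_yield"),
    shoulder_yield = num_field("shoulder_yield"),
    total_yield = num_field("total_yield"),
    prop_leg = num_field("prop_leg"),
    prop_loin = num_field("prop_loin"),
    prop_shoulder = num_field("prop_shoulder"),
    stringsAsFactors = FALSE)

  # growth rate: explicit column wins; otherwise recompute from weights
  has_explicit <- col_map[["growth_rate"]] %in% names(raw)
  computable <- !is.na(rec$birth_weight) & !is.na(rec$weaning_weight) &
    !is.na(rec$age_weaning) & rec$age_weaning > 0
  if (has_explicit) {
    both <- sum(computable & !is.na(rec$growth_rate))
    if (both > 0L) {
      note("", "growth_rate",
           paste0("explicit growth-rate column present; recomputation ",
                  "from weights skipped for ", both, " row(s)"), "info")
    }
  } else {
    rec$growth_rate[computable] <- compute_growth_rate(
      rec$birth_weight[computable], rec$weaning_weight[computable],
      rec$age_weaning[computable])
  }

  # carcass phenotypes are defined for slaughtered males only
  female_carcass <- which(rec$gender %in% "female" &
                            rowSums(!is.na(rec[CARCASS_FIELDS])) > 0L)
  for (i in female_carcass) {
    note(rec$animal_id[i], "carcass",
         "carcass phenotypes cleared: animal is female", "repaired")
    rec[i, CARCASS_FIELDS] <- NA_real_
  }

  # composition: always derived from the three regional yields
  parts_ok <- !is.na(rec$leg_yield) & !is.na(rec$loin_yield) &
    !is.na(rec$shoulder_yield) &
    (rec$leg_yield + rec$loin_yield + rec$shoulder_yield) > 0
  if (any(parts_ok)) {
    comp <- derive_composition(rec$leg_yield[parts_ok],
                               rec$loin_yield[parts_ok],
                               rec$shoulder_yield[parts_ok])
    for (f in c("total_yield", "prop_leg", "prop_loin", "prop_shoulder")) {
      old <- rec[[f]][parts_ok]
      new <- comp[[f]]
      mismatch <- which(!is.na(old) & abs(old - new) > 1e-6)
      for (j in mismatch) {
        note(rec$animal_id[parts_ok][j], f,
             sprintf("stored value %.4f disagrees with derived %.4f; derived kept",
                     old[j], new[j]), "repaired")
      }
      rec[[f]][parts_ok] <- new
    }
  }

  report <- if (length(report)) do.call(rbind, report) else
    data.frame(animal_id = character(), field = character(),
               message = character(), action = character(),
               stringsAsFactors = FALSE)

  structure(list(records = rec[!exclude, , drop = FALSE], report = report),
            class = "animal_table")
}

#' @export
print.animal_table <- function(x, ...) {
  cat("Animal table:", nrow(x$records), "record(s),",
      sum(x$report$action == "excluded"), "exclusion note(s)\n")
  invisible(x)
}

#' Write an animal table to delimited text
#'
#' Writes records in the exact format [read_animal_table()] consumes.
#' Numeric cells use 17 significant digits so that a write/read round trip
#' reproduces every parsed value bit-exactly; missing cells are empty
#' strings.
#'
#' @param records data frame of animal records (the `records` component of
#'   an `"animal_table"`, or a compatible frame).
#' @param path output file path.
#' @param sep field separator, `"\t"` (default) or `","`.
#' @return `path`, invisibly.
#' @export
write_animal_table <- function(records, path, sep = "\t") {
  out <- records
  for (cn in names(out)) {
    if (is.numeric(out[[cn]])) {
      v <- sprintf("%.17g", out[[cn]])
      v[is.na(out[[cn]])] <- ""
      # integers render without exponent noise
      int <- !is.na(out[[cn]]) & out[[cn]] == round(out[[cn]]) &
        abs(out[[cn]]) < 1e15
      v[int] <- sprintf("%.0f", out[[cn]][int])
      out[[cn]] <- v
    } else {
      out[[cn]][is.na(out[[cn]])] <- ""
    }
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a validation report to delimited text
#'
#' @param report the `report` component of an `"animal_table"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Pre-weaning growth rate
#'
#' Growth rate is weight gained per day of age between birth and weaning,
#' expressed in grams per day: `(weaning - birth) * 1000 / age`.
#'
#' @param birth_weight birth weight, kg.
#' @param weaning_weight weaning weight, kg.
#' @param age age at weaning, days (must be positive).
#' @return growth rate in g/day (vectorized).
#' @examples
#' compute_growth_rate(5.0, 32.0, 100)  # 270 g/day
#' @export
compute_growth_rate <- function(birth_weight, weaning_weight, age) {
  if (any(!is.finite(age)) || any(age <= 0)) {
    stop("age must be a positive number of days", call. = FALSE)
  }
  (weaning_weight - birth_weight) * 1000 / age
}

#' Total lean-meat yield and proportion yields
#'
#' Total lean-meat yield is the sum of the leg, loin and shoulder lean-meat
#' yields (each a percentage of hot carcass weight).  The proportion yield
#' of a region is that region's yield divided by the total, expressed as a
#' percentage; the three proportions sum to 100 by construction.
#'
#' @param leg,loin,shoulder regional lean-meat yields, \% of hot carcass
#'   weight; all must be non-negative with a positive sum.
#' @return A data frame with columns `total_yield`, `prop_leg`, `prop_loin`,
#'   `prop_shoulder` (vectorized).
#' @examples
#' derive_composition(20, 14, 16)
#' @export
derive_composition <- function(leg, loin, shoulder) {
  if (any(leg < 0 | loin < 0 | shoulder < 0, na.rm = TRUE)) {
    stop("regional yields must be non-negative", call. = FALSE)
  }
  total <- leg + loin + shoulder
  if (any(total <= 0, na.rm = TRUE)) {
    stop("total yield must be positive", call. = FALSE)
  }
  data.frame(total_yield = total,
             prop_leg = leg / total * 100,
             prop_loin = loin / total * 100,
             prop_shoulder = shoulder / total * 100)
}
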