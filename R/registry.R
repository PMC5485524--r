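#' Variant registry for the two amplified gene regions
#'
#' A registry declares which variant labels are legal for each of the two
#' regions typed in the cohort: the promoter--exon 1 fragment
#' (`PROM_EX1`) and the intron 2--exon 3 fragment (`INT2_EX3`).  The
#' default registry carries the variants observed in the ovine adiponectin
#' gene: four promoter--exon 1 variants (A1, B1, C1, D1) and three
#' intron 2--exon 3 variants (A3, B3, C3).  The registry is extensible so
#' that newly described variants can be admitted without touching any code.
#'
#' @param prom_ex1 character vector of legal labels for the promoter--exon 1
#'   region.
#' @param int2_ex3 character vector of legal labels for the intron 2--exon 3
#'   region.
#' @return A named list with components `PROM_EX1` and `INT2_EX3`, of class
#'   `"variant_registry"`.
#' @examples
#' reg <- variant_registry()
#' reg$PROM_EX1
#' # admit a new promoter variant:
#' variant_registry(prom_ex1 = c(reg$PROM_EX1, "E1"))
#' @export
variant_registry <- function(prom_ex1 = c("A1", "B1", "C1", "D1"),
                             int2_ex3 = c("A3", "B3", "C3")) {
  for (v in list(prom_ex1, int2_ex3)) {
    if (!is.character(v) || length(v) < 1L || anyDuplicated(v) ||
        any(!nzchar(v)) || any(grepl("[-/|–—[:space:]]", v))) {
      stop("variant labels must be unique, non-empty strings without ",
           "'-', '/', '|' or whitespace", call. = FALSE)
    }
  }
  structure(list(PROM_EX1 = prom_ex1, INT2_EX3 = int2_ex3),
            class = "variant_registry")
}

#' @export
print.variant_registry <- function(x, ...) {
  cat("Variant registry\n")
  cat("  PROM_EX1:", paste(x$PROM_EX1, collapse = ", "), "\n")
  cat("  INT2_EX3:", paste(x$INT2_EX3, collapse = ", "), "\n")
  invisible(x)
}

# Normalize haplotype separators: en/em dash accepted on input, ASCII "-"
# used everywhere internally and in machine-readable output.
normalize_hap <- function(x) {
  gsub("–|—", "-", trimws(x))
}

#' Construct haplotype identifiers
#'
#' A haplotype is a promoter--exon 1 variant co-inherited with an
#' intron 2--exon 3 variant on one chromosome, written `"A1-A3"`.  The two
#' regions are treated as fully linked: no recombination between them is
#' modelled anywhere in the package.
#'
#' @param prom promoter--exon 1 variant label(s).
#' @param coding intron 2--exon 3 variant label(s).
#' @param registry a [variant_registry()].
#' @return character vector of haplotype identifiers.
#' @examples
#' haplotype("A1", "A3")
#' @export
haplotype <- function(prom, coding, registry = variant_registry()) {
  if (any(!prom %in% registry$PROM_EX1)) {
    stop("unknown variant ", paste(setdiff(prom, registry$PROM_EX1),
                                   collapse = ", "),
         " for PROM_EX1", call. = FALSE)
  }
  if (any(!coding %in% registry$INT2_EX3)) {
    stop("unknown variant ", paste(setdiff(coding, registry$INT2_EX3),
                                   collapse = ", "),
         " for INT2_EX3", call. = FALSE)
  }
  paste0(prom, "-", coding)
}

#' Split haplotype identifiers into their two region variants
#'
#' @param hap character vector of haplotype identifiers (`"A1-A3"`; en dash
#'   accepted).
#' @return A two-column character matrix with columns `prom` and `coding`.
#' @export
hap_split <- function(hap) {
  parts <- strsplit(normalize_hap(hap), "-", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop("malformed haplotype identifier: ",
         paste(hap[bad], collapse = ", "), call. = FALSE)
  }
  m <- do.call(rbind, parts)
  colnames(m) <- c("prom", "coding")
  m
}

#' Construct canonical diplotype identifiers
#'
#' A diplotype is the unordered pair of haplotypes carried by one animal,
#' written `"A1-A3/B1-A3"`.  The pair is stored in lexicographic order so
#' that `{h1, h2}` and `{h2, h1}` produce identical strings; homozygous
#' diplotypes (`"A1-A3/A1-A3"`) are legal.
#'
#' @param h1,h2 haplotype identifiers (vectorized).
#' @return character vector of canonical diplotype identifiers.
#' @examples
#' diplotype("B1-A3", "A1-A3")  # canonicalized to "A1-A3/B1-A3"
#' @export
diplotype <- function(h1, h2) {
  h1 <- normalize_hap(h1)
  h2 <- normalize_hap(h2)
  ifelse(h1 <= h2, paste0(h1, "/", h2), paste0(h2, "/", h1))
}

#' Split diplotype identifiers into their two haplotypes
#'
#' @param dip character vector of diplotype identifiers.
#' @return A two-column character matrix, one row per diplotype.
#' @export
dip_haps <- function(dip) {
  parts <- strsplit(normalize_hap(dip), "/", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop("malformed diplotype identifier: ",
         paste(dip[bad], collapse = ", "), call. = FALSE)
  }
  m <- do.call(rbind, parts)
  colnames(m) <- c("hap1", "hap2")
  m
}

#' Construct a canonical unphased region genotype
#'
#' An unphased genotype at one amplified region is the unordered pair of
#' variant labels observed there, written `"A1/B1"` with the labels sorted.
#'
#' @param a,b variant labels (vectorized).
#' @param region `"PROM_EX1"` or `"INT2_EX3"`.
#' @param registry a [variant_registry()].
#' @return character vector of canonical genotype strings.
#' @examples
#' region_genotype("B1", "A1", "PROM_EX1")  # "A1/B1"
#' @export
region_genotype <- function(a, b, region = c("PROM_EX1", "INT2_EX3"),
                            registry = variant_registry()) {
  region <- match.arg(region)
  legal <- registry[[region]]
  bad <- setdiff(c(a, b), legal)
  if (length(bad)) {
    stop("unknown variant ", paste(bad, collapse = ", "), " for ", region,
         call. = FALSE)
  }
  ifelse(a <= b, paste0(a, "/", b), paste0(b, "/", a))
}

# Parse a "label/label" genotype cell; returns list(value=..., error=...)
# with value NA and an error message when the cell is malformed or carries
# an unregistered label.  Empty cells parse to NA without error.
parse_genotype <- function(x, region, registry) {
  x <- trimws(x)
  if (is.na(x) || !nzchar(x)) {
    return(list(value = NA_character_, error = NULL))
  }
  parts <- strsplit(x, "/", fixed = TRUE)[[1L]]
  if (length(parts) != 2L || any(!nzchar(parts))) {
    return(list(value = NA_character_,
                error = paste0("malformed genotype '", x, "'")))
  }
  legal <- registry[[region]]
  bad <- setdiff(parts, legal)
  if (length(bad)) {
    return(list(value = NA_character_,
                error = paste0("unknown variant ", paste(bad, collapse = ", "),
                               " for ", region)))
  }
  list(value = region_genotype(parts[1L], parts[2L], region, registry),
       error = NULL)
}

#' Collapse a diplotype to its two unphased region genotypes
#'
#' The region-wise collapse of a diplotype is the pair of unordered
#' genotypes that typing each region separately would observe.  Phasing is
#' only ever accepted when this collapse reproduces the observed genotypes
#' exactly.
#'
#' @param dip character vector of diplotype identifiers.
#' @return A data frame with columns `genotype_prom` and `genotype_coding`.
#' @examples
#' collapse_diplotype("A1-A3/B1-C3")
#' @export
collapse_diplotype <- function(dip) {
  hm <- dip_haps(dip)
  h1 <- hap_split(hm[, "hap1"])
  h2 <- hap_split(hm[, "hap2"])
  data.frame(
    genotype_prom = ifelse(h1[, "prom"] <= h2[, "prom"],
                           paste0(h1[, "prom"], "/", h2[, "prom"]),
                           paste0(h2[, "prom"], "/", h1[, "prom"])),
    genotype_coding = ifelse(h1[, "coding"] <= h2[, "coding"],
                             paste0(h1[, "coding"], "/", h2[, "coding"]),
                             paste0(h2[, "coding"], "/", h1[, "coding"])),
    stringsAsFactors = FALSE
  )
}

# The documented SNP position catalogue for the two regions.  Annotation is
# descriptive metadata only: phasing and association never consult it.
snp_position_catalogue <- function() {
  list(
    PROM_EX1 = c("c.-9831" = "A/G", "c.-9791" = "C/T", "c.-9790" = "G/T",
                 "c.-9644" = "G/A", "c.-9640" = "A/G", "c.-9632" = "C/T",
                 "c.-9631" = "A/G"),
    INT2_EX3 = c("c.225" = "T/C", "c.387" = "A/G", "c.515" = "G/A")
  )
}

#' Attach SNP annotation to a variant label
#'
#' Records, for a region variant, the nucleotide state it carries at each of
#' the documented SNP positions of its region (HGVS-style coordinates).
#' Annotation is purely descriptive; no phasing or association logic reads
#' it.
#'
#' @param label variant label, e.g. `"A1"`.
#' @param region `"PROM_EX1"` or `"INT2_EX3"`.
#' @param states named character vector mapping position strings (e.g.
#'   `"c.-9831"`, `"c.515"`) to single nucleotide states; positions must
#'   belong to the documented catalogue for the region.
#' @return An object of class `"snp_annotation"`.
#' @examples
#' snp_annotation("A3", "INT2_EX3", c("c.515" = "G"))
#' @export
snp_annotation <- function(label, region = c("PROM_EX1", "INT2_EX3"),
                           states = character()) {
  region <- match.arg(region)
  catalogue <- snp_position_catalogue()[[region]]
  if (length(states)) {
    bad <- setdiff(names(states), names(catalogue))
    if (length(bad)) {
      stop("positions not in the documented catalogue for ", region, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(label = label, region = region, states = states),
            class = "snp_annotation")
}

#' @export
print.snp_annotation <- function(x, ...) {
  cat("SNP annotation for variant", x$label, sprintf("(%s)\n", x$region))
  if (length(x$states)) {
    for (p in names(x$states)) cat(" ", p, "=", x$states[[p]], "\n")
  } else {
    cat("  (no states recorded)\n")
  }
  invisible(x)
}
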