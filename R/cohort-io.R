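#' Write a cohort to VCF 4.2
#'
#' Emits GT for every sample (phased `a|b` where haplotype assignment is
#' known, `a/b` otherwise, `./.` for missing) plus a `PP` FORMAT field holding
#' the phasing probability of phased heterozygous genotypes (4 decimals). The
#' gene assignment travels in an INFO `GENE` tag so that
#' [read_vcf()] round-trips the full data model.
#'
#' @param cohort A [rare_cohort()].
#' @param path Output file path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(cohort, path) {
  sites <- cohort$sites
  gt <- cohort$gt
  n <- length(cohort$samples)
  m <- nrow(sites)
  has_pp <- !is.null(cohort$pp)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=autoburden",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene assignment\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=PP,Number=1,Type=Float,Description=\"Phasing probability for phased heterozygous genotypes\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$samples), collapse = "\t"))
  gt_str <- matrix("./.", n, m)
  known <- !is.na(gt)
  if (!is.null(cohort$hap1)) {
    h1 <- cohort$hap1; h2 <- cohort$hap2
    phased <- known & !is.na(h1) & !is.na(h2)
    gt_str[phased] <- paste0(h1[phased], "|", h2[phased])
    unph <- known & !phased
    gt_str[unph] <- c("0/0", "0/1", "1/1")[gt[unph] + 1L]
  } else {
    gt_str[known] <- c("0/0", "0/1", "1/1")[gt[known] + 1L]
  }
  if (has_pp) {
    with_pp <- !is.na(cohort$pp)
    gt_str[with_pp] <- sprintf("%s:%.4f", gt_str[with_pp], cohort$pp[with_pp])
    fmt <- ifelse(colSums(with_pp) > 0, "GT:PP", "GT")
  } else {
    fmt <- rep("GT", m)
  }
  body <- vapply(seq_len(m), function(j) {
    paste(c(sites$chrom[j], sites$pos[j], sites$variant_key[j], sites$ref[j],
            sites$alt[j], ".", "PASS", paste0("GENE=", sites$gene[j]),
            fmt[j], gt_str[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF into the cohort data model
#'
#' Parses GT (and the optional PP phasing-probability FORMAT tag) with
#' \pkg{vcfR}. Phased entries `a|b` populate the haplotype matrices; `./.`
#' becomes a missing genotype excluded from AC/AN. Multi-allelic records must
#' be split beforehand.
#'
#' @param path VCF file (4.x, GT required).
#' @param region Optional filter `list(chrom =, from =, to =)` applied to sites.
#' @return A [rare_cohort()].
#' @export
read_vcf <- function(path, region = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    abort("multi-allelic record(s) found; split/normalize them first (e.g. bcftools norm -m-)")
  }
  info <- fix$INFO
  gene <- sub(".*GENE=([^;]+).*", "\\1", info)
  gene[!grepl("GENE=", info)] <- NA_character_
  sites <- tibble(
    variant_key = paste(fix$CHROM, fix$POS, fix$REF, fix$ALT, sep = ":"),
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, gene = gene)
  keep <- rep(TRUE, nrow(sites))
  if (!is.null(region)) {
    keep <- sites$chrom == region$chrom &
      sites$pos >= region$from & sites$pos <= region$to
  }
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  pp_raw <- if ("PP" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) {
    vcfR::extract.gt(v, element = "PP", as.numeric = TRUE)
  } else NULL
  samples <- colnames(gt_raw)
  m <- nrow(sites); n <- length(samples)
  parse_mat <- function(raw) {
    # raw is sites x samples character
    a1 <- substr(raw, 1, 1)
    sep <- substr(raw, 2, 2)
    a2 <- substr(raw, 3, 3)
    miss <- is.na(raw) | a1 == "."
    gt <- suppressWarnings(as.integer(a1) + as.integer(a2))
    gt[miss] <- NA_integer_
    phased <- !miss & sep == "|"
    h1 <- suppressWarnings(as.integer(a1)); h1[!phased] <- NA_integer_
    h2 <- suppressWarnings(as.integer(a2)); h2[!phased] <- NA_integer_
    list(gt = gt, h1 = h1, h2 = h2)
  }
  p <- parse_mat(gt_raw)
  shape <- function(x) matrix(x, n, m, byrow = TRUE,
                              dimnames = list(samples, sites$variant_key))
  gt <- shape(p$gt); h1 <- shape(p$h1); h2 <- shape(p$h2)
  pp <- if (is.null(pp_raw)) NULL else shape(as.numeric(pp_raw))
  out <- rare_cohort(samples, sites[keep, , drop = FALSE],
                     gt[, keep, drop = FALSE],
                     hap1 = h1[, keep, drop = FALSE],
                     hap2 = h2[, keep, drop = FALSE],
                     pp = if (is.null(pp)) NULL else pp[, keep, drop = FALSE])
  out
}

read_tsv_checked <- function(path, required, what) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    abort(sprintf("%s table missing mandatory column(s): %s",
                  what, paste(missing_cols, collapse = ", ")))
  }
  tab
}

#' Read and validate phenotype / covariate / annotation / drug tables
#'
#' All tables are TSV with a header row. Phenotype and covariate tables are
#' joined (inner) against the cohort's sample ids; dropped ids are reported
#' with a warning. Duplicate sample ids are an error.
#'
#' @param path File path.
#' @param cohort Optional [rare_cohort()] to validate sample ids against.
#' @return A tibble.
#' @name read_tables
NULL

#' @rdname read_tables
#' @export
read_phenotypes <- function(path, cohort = NULL) {
  tab <- read_tsv_checked(path, "sample_id", "phenotype")
  check_sample_table(tab, cohort, "phenotype")
}

#' @rdname read_tables
#' @export
read_covariates <- function(path, cohort = NULL) {
  tab <- read_tsv_checked(path, "sample_id", "covariate")
  check_sample_table(tab, cohort, "covariate")
}

check_sample_table <- function(tab, cohort, what) {
  if (anyDuplicated(tab$sample_id)) {
    abort(sprintf("duplicated sample id(s) in %s table", what))
  }
  if (!is.null(cohort)) {
    dropped <- sum(!tab$sample_id %in% cohort$samples)
    if (dropped > 0) {
      warn(sprintf("%d sample id(s) in %s table not in cohort; dropped on join",
                   dropped, what))
      tab <- filter(tab, .data$sample_id %in% cohort$samples)
    }
  }
  tab
}

#' @rdname read_tables
#' @export
read_annotation <- function(path) {
  read_tsv_checked(path,
                   c("variant_key", "gene", "consequence", "lof_confidence",
                     "cadd", "polyphen", "sift_call", "ref_panel_ac",
                     "ref_panel_an"),
                   "annotation")
}

#' @rdname read_tables
#' @export
read_drug_table <- function(path) {
  tab <- read_tsv_checked(path,
                          c("drug_id", "target_genes", "max_phase",
                            "action_type", "indication_class"),
                          "drug")
  stopifnot(all(tab$max_phase %in% 1:4))
  tab
}

#' Annotation table of a simulated cohort
#'
#' Formats the generator's site annotations (consequence class, damage-score
#' surrogates, reference-panel allele counts derived from the true MAF) in the
#' schema [read_annotation()] expects.
#'
#' @param cohort A simulated [rare_cohort()].
#' @param ref_panel_an Reference panel allele number used to synthesize
#'   reference allele counts from the true MAF.
#' @return A tibble.
#' @export
annotation_table <- function(cohort, ref_panel_an = 400000L) {
  sites <- cohort$sites
  stopifnot("consequence" %in% names(sites))
  ref_af <- if ("true_maf" %in% names(sites)) sites$true_maf else sites$af
  tibble(
    variant_key = sites$variant_key,
    gene = sites$gene,
    consequence = sites$consequence,
    lof_confidence = if_else(sites$consequence == "pLoF-HC", "HC",
                             if_else(sites$consequence == "pLoF-LC", "LC",
                                     NA_character_)),
    cadd = sites$cadd,
    polyphen = sites$polyphen,
    sift_call = sites$sift_call,
    ref_panel_ac = as.integer(round(ref_af * ref_panel_an)),
    ref_panel_an = as.integer(ref_panel_an))
}
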