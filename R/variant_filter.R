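#' Caller FILTER rule for somatic SNVs
#'
#' Per-caller allowed FILTER values: `"PASS"` only for VarScan2 and
#' SomaticSniper; `"PASS"` or `"panel_of_normals"` for Mutect2; `"Tier1"`
#' through `"Tier5"` for MuSe.
#'
#' @param caller Character vector of caller names (one of `MuSe`, `Mutect2`,
#'   `VarScan2`, `SomaticSniper`).
#' @param filter_status Character vector of FILTER values.
#' @return Logical vector: record passes the caller rule.
#' @export
caller_filter_pass <- function(caller, filter_status) {
  allowed <- list(
    MuSe = paste0("Tier", 1:5),
    Mutect2 = c("PASS", "panel_of_normals"),
    VarScan2 = "PASS",
    SomaticSniper = "PASS"
  )
  unknown <- setdiff(unique(caller), names(allowed))
  if (length(unknown)) {
    stop("unknown caller(s): ", paste(unknown, collapse = ", "))
  }
  mapply(function(c, f) f %in% allowed[[c]], caller, filter_status,
         USE.NAMES = FALSE)
}

#' Population allele-frequency rule with COSMIC rescue
#'
#' A record fails when its 1000 Genomes or ExAC frequency exceeds 0.01 and it
#' is not reported in COSMIC. Missing frequencies count as 0.
#'
#' @param af_1000g,af_exac Population allele frequencies (NA allowed).
#' @param in_cosmic Logical: reported in COSMIC.
#' @return Logical vector: record passes.
#' @export
population_filter_pass <- function(af_1000g, af_exac, in_cosmic) {
  af1 <- ifelse(is.na(af_1000g), 0, af_1000g)
  af2 <- ifelse(is.na(af_exac), 0, af_exac)
  !((af1 > 0.01 | af2 > 0.01) & !in_cosmic)
}

#' Tumor/normal coverage rule
#'
#' Keeps records with at least 6 reads in the normal of which at most 1
#' reports the alternative allele (or normal VAF < 0.01), and at least 8
#' reads in the tumor of which at least 3 report the variant (or tumor
#' VAF > 0.2). Both VAF comparisons are strict. Zero depth fails (no error).
#'
#' @param normal_depth,normal_alt,tumor_depth,tumor_alt Read counts.
#' @return Logical vector: record passes.
#' @export
coverage_filter_pass <- function(normal_depth, normal_alt,
                                 tumor_depth, tumor_alt) {
  n_vaf <- ifelse(normal_depth > 0, normal_alt / normal_depth, NA_real_)
  t_vaf <- ifelse(tumor_depth > 0, tumor_alt / tumor_depth, NA_real_)
  normal_ok <- normal_depth >= 6 &
    (normal_alt <= 1 | (!is.na(n_vaf) & n_vaf < 0.01))
  tumor_ok <- tumor_depth >= 8 &
    (tumor_alt >= 3 | (!is.na(t_vaf) & t_vaf > 0.2))
  normal_ok & tumor_ok
}

#' Build the protected or public somatic mutation set
#'
#' Indels are removed in both modes. The public set is the plain union of the
#' per-caller SNVs. The protected set keeps records passing the caller FILTER
#' rule, the population-frequency/COSMIC rule and the coverage rule, then
#' deduplicates by `mutation_id` keeping the record with the highest tumor
#' depth.
#'
#' @param records A variant-record `data.frame` (rows from all callers; must
#'   have a `caller` column) or a list of per-caller data frames.
#' @param mode `"protected"` or `"public"`.
#' @return The filtered, deduplicated `data.frame`, with an attribute
#'   `"report"`: named counts of input records and removals per rule.
#' @export
build_mutation_sets <- function(records, mode = c("protected", "public")) {
  mode <- match.arg(mode)
  if (is.list(records) && !is.data.frame(records)) {
    records <- do.call(rbind, records)
  }
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    warning("empty variant input; returning empty set")
    return(structure(records, report = c(input = 0L)))
  }
  report <- c(input = nrow(records))
  snv <- records[!records$is_indel, , drop = FALSE]
  report["removed_indel"] <- nrow(records) - nrow(snv)
  if (mode == "protected") {
    cp <- caller_filter_pass(snv$caller, snv$filter_status)
    snv <- snv[cp, , drop = FALSE]
    report["removed_caller_filter"] <- sum(!cp)
    pp <- population_filter_pass(snv$af_1000g, snv$af_exac, snv$in_cosmic)
    snv <- snv[pp, , drop = FALSE]
    report["removed_population"] <- sum(!pp)
    vp <- coverage_filter_pass(snv$normal_depth, snv$normal_alt,
                               snv$tumor_depth, snv$tumor_alt)
    snv <- snv[vp, , drop = FALSE]
    report["removed_coverage"] <- sum(!vp)
  }
  # union across callers: dedupe by mutation_id, keep max tumor depth
  ord <- order(snv$mutation_id, -snv$tumor_depth)
  snv <- snv[ord, , drop = FALSE]
  snv <- snv[!duplicated(snv$mutation_id), , drop = FALSE]
  rownames(snv) <- NULL
  report["kept"] <- nrow(snv)
  structure(snv, report = report)
}

#' Read one caller's VCF into a variant-record table
#'
#' Expects a tumor/normal pair VCF with `AD` (ref,alt) and `DP` FORMAT fields
#' and sample columns named (or ordered as) NORMAL, TUMOR. Population
#' frequencies are read from INFO tags `AF1KG` and `AFEXAC`, the COSMIC flag
#' from the `COSMIC` INFO flag, and the caller from the `Caller` INFO tag
#' unless given explicitly.
#'
#' @param path VCF file (plain or gzipped).
#' @param caller Optional caller name overriding the `Caller` INFO tag.
#' @return A variant-record `data.frame` (see [simulate_read_counts()] for
#'   columns); positions are 1-based as in the VCF.
#' @export
read_caller_vcf <- function(path, caller = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  n <- nrow(fix)
  info_tag <- function(tag) {
    x <- vcfR::extract.info(v, element = tag)
    suppressWarnings(as.numeric(x))
  }
  info_chr <- function(tag) vcfR::extract.info(v, element = tag)
  ad <- vcfR::extract.gt(v, element = "AD")
  dp <- vcfR::extract.gt(v, element = "DP")
  cols <- colnames(ad)
  normal_col <- if ("NORMAL" %in% cols) "NORMAL" else cols[1]
  tumor_col <- if ("TUMOR" %in% cols) "TUMOR" else cols[2]
  alt_of <- function(x) as.integer(vapply(strsplit(x, ","), `[`, "", 2L))
  caller_col <- if (is.null(caller)) info_chr("Caller") else rep(caller, n)
  cosmic <- grepl("(^|;)COSMIC(;|$|=)", v@fix[, "INFO"])
  pos <- as.integer(fix$POS)
  data.frame(
    mutation_id = paste(fix$CHROM, pos, fix$REF, fix$ALT, sep = ":"),
    chrom = fix$CHROM,
    pos = pos,
    ref = fix$REF,
    alt = fix$ALT,
    is_indel = nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L,
    caller = caller_col,
    filter_status = fix$FILTER,
    af_1000g = info_tag("AF1KG"),
    af_exac = info_tag("AFEXAC"),
    in_cosmic = cosmic,
    normal_depth = as.integer(dp[, normal_col]),
    normal_alt = alt_of(ad[, normal_col]),
    tumor_depth = as.integer(dp[, tumor_col]),
    tumor_alt = alt_of(ad[, tumor_col]),
    stringsAsFactors = FALSE
  )
}

#' Write a variant-record table as a tumor/normal VCF
#'
#' Mirrors the layout read by [read_caller_vcf()]: AD/DP FORMAT fields for
#' NORMAL and TUMOR columns, caller and population annotations in INFO.
#'
#' @param variants Variant-record `data.frame`.
#' @param path Output path; vcfR writes gzip-compressed VCF.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path) {
  n <- nrow(variants)
  num_or_dot <- function(x) ifelse(is.na(x), NA_character_, format(x))
  info <- paste0("Caller=", variants$caller)
  af1 <- num_or_dot(variants$af_1000g)
  af2 <- num_or_dot(variants$af_exac)
  info <- ifelse(is.na(af1), info, paste0(info, ";AF1KG=", af1))
  info <- ifelse(is.na(af2), info, paste0(info, ";AFEXAC=", af2))
  info <- ifelse(variants$in_cosmic, paste0(info, ";COSMIC"), info)
  fix <- cbind(
    CHROM = as.character(variants$chrom), POS = as.character(variants$pos),
    ID = variants$mutation_id, REF = variants$ref, ALT = variants$alt,
    QUAL = ".", FILTER = variants$filter_status, INFO = info)
  gt_fmt <- function(depth, alt) {
    paste0(depth - alt, ",", alt, ":", depth)
  }
  gt <- cbind(
    FORMAT = rep("AD:DP", n),
    NORMAL = gt_fmt(variants$normal_depth, variants$normal_alt),
    TUMOR = gt_fmt(variants$tumor_depth, variants$tumor_alt))
  meta <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=Caller,Number=1,Type=String,Description=\"Variant caller\">",
    "##INFO=<ID=AF1KG,Number=1,Type=Float,Description=\"1000 genomes allele frequency\">",
    "##INFO=<ID=AFEXAC,Number=1,Type=Float,Description=\"ExAC allele frequency\">",
    "##INFO=<ID=COSMIC,Number=0,Type=Flag,Description=\"Reported in COSMIC\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">")
  vcf <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(vcf, file = path)
  invisible(path)
}
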