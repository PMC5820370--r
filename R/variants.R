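#' Annotated multi-sample variant sets
#'
#' A `variant_set` bundles the per-site annotations and the per-sample
#' genotypes of a set of biallelic small variants:
#' \describe{
#'   \item{`variants`}{data frame with `chrom`, `pos` (1-based), `ref`,
#'     `alt`, `gene`, `transcript`, `cdna_change`, `protein_change`
#'     (HGVS `p.` string or `NA`), `consequence`, `phylop` (`NA` =
#'     unannotated, distinct from 0), `inhouse_freq`.}
#'   \item{`pop_af`}{numeric matrix, one column per population-frequency
#'     source (e.g. `AF_EVS`, `AF_DBSNP`, `AF_G1K`); `NA` = variant not
#'     observed in that source.}
#'   \item{`geno`}{character matrix (variants x samples) with entries
#'     `"hom_ref"`, `"het"`, `"hom_alt"` or `NA` (missing call).}
#' }
#' Consequence takes one of `"nonsynonymous"`, `"synonymous"`,
#' `"canonical_splice"`, `"utr"`, `"intronic"`, `"intergenic"`, `"other"`.
#'
#' @param variants,pop_af,geno See description.
#' @return An object of class `variant_set`.
#' @export
variant_set <- function(variants, pop_af, geno) {
  stopifnot(is.data.frame(variants))
  req <- c("chrom", "pos", "ref", "alt", "gene", "transcript",
           "cdna_change", "protein_change", "consequence", "phylop",
           "inhouse_freq")
  missing_cols <- setdiff(req, names(variants))
  if (length(missing_cols))
    stop("variants table lacks columns: ", paste(missing_cols, collapse = ", "))
  n <- nrow(variants)
  pop_af <- as.matrix(pop_af)
  geno <- as.matrix(geno)
  if (nrow(pop_af) != n || nrow(geno) != n)
    stop("pop_af and geno must have one row per variant")
  if (any(variants$pos < 1)) stop("positions must be >= 1")
  if (any(variants$ref == variants$alt)) stop("ref and alt alleles must differ")
  if (any(!is.na(pop_af) & (pop_af < 0 | pop_af > 1)))
    stop("population allele frequencies must lie in [0, 1]")
  bad_cons <- setdiff(unique(variants$consequence), exolink_consequences)
  if (length(bad_cons))
    stop("unknown consequence class(es): ", paste(bad_cons, collapse = ", "))
  ok_gt <- is.na(geno) | geno %in% c("hom_ref", "het", "hom_alt")
  if (!all(ok_gt)) stop("genotypes must be hom_ref/het/hom_alt/NA")
  has_prot <- !is.na(variants$protein_change) & variants$protein_change != ""
  if (any(has_prot & variants$consequence != "nonsynonymous"))
    stop("protein_change implies consequence 'nonsynonymous'")
  structure(list(variants = variants, pop_af = pop_af, geno = geno),
            class = "variant_set")
}

#' Recognised consequence classes
#' @export
exolink_consequences <- c("nonsynonymous", "synonymous", "canonical_splice",
                          "utr", "intronic", "intergenic", "other")

#' @export
print.variant_set <- function(x, ...) {
  cat("variant_set:", nrow(x$variants), "variants x", ncol(x$geno),
      "samples;", ncol(x$pop_af), "AF sources\n")
  invisible(x)
}

#' @export
length.variant_set <- function(x) nrow(x$variants)

#' Subset a variant set by row
#' @param x A [variant_set()].
#' @param i Row index.
#' @param ... Unused.
#' @export
`[.variant_set` <- function(x, i, ...) {
  variant_set(x$variants[i, , drop = FALSE],
              x$pop_af[i, , drop = FALSE],
              x$geno[i, , drop = FALSE])
}

#' Variant keys (chrom:pos:ref:alt)
#' @param x A [variant_set()].
#' @return Character vector of unique record keys.
#' @export
variant_keys <- function(x) {
  with(x$variants, paste(chrom, pos, ref, alt, sep = ":"))
}

# INFO keys used by the annotated-VCF dialect.
.info_fixed <- c(GENE = "gene", TX = "transcript", CDNA = "cdna_change",
                 PROT = "protein_change", CSQ = "consequence")

#' Read an annotated multi-sample VCF
#'
#' Reads a VCF v4.2 carrying its functional annotations in INFO keys:
#' `GENE`, `TX`, `CDNA`, `PROT`, `CSQ` (consequence class), `PHYLOP`,
#' `AF_INHOUSE`, and any number of population-frequency keys matching
#' `AF_<SOURCE>`. Multiallelic records must be pre-split (e.g. with
#' `bcftools norm -m-`). Absent INFO keys yield `NA` fields — an
#' unobserved frequency is never coerced to zero.
#'
#' @param path VCF path (plain text or bgzip).
#' @param samples Sample ids to load; default all samples in the file.
#' @return A [variant_set()].
#' @export
read_annotated_vcf <- function(path, samples = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) && any(grepl(",", fix[, "ALT"], fixed = TRUE)))
    stop("multiallelic record at ", fix[grepl(",", fix[, "ALT"]), "CHROM"][1],
         ":", fix[grepl(",", fix[, "ALT"]), "POS"][1],
         "; pre-split multiallelics (e.g. 'bcftools norm -m-') first")

  header_info <- grep("^##INFO=<ID=", v@meta, value = TRUE)
  declared <- sub("^##INFO=<ID=([^,]+),.*$", "\\1", header_info)
  info_str <- if (nrow(fix)) unname(fix[, "INFO"]) else character(0)
  used <- unique(unlist(lapply(strsplit(info_str, ";", fixed = TRUE),
                               function(kv) sub("=.*$", "", kv))))
  used <- setdiff(used, c("", "."))
  undeclared <- setdiff(used, declared)
  if (length(undeclared))
    stop("INFO key(s) used but not declared in the VCF header: ",
         paste(undeclared, collapse = ", "))

  vcf_samples <- colnames(v@gt)[-1]
  if (is.null(samples)) samples <- vcf_samples
  absent <- setdiff(samples, vcf_samples)
  if (length(absent))
    stop("sample(s) not in VCF: ", paste(absent, collapse = ", "),
         "; available: ", paste(vcf_samples, collapse = ", "))

  info_get <- function(key) {
    vapply(strsplit(info_str, ";", fixed = TRUE), function(kv) {
      hit <- grep(paste0("^", key, "="), kv, value = TRUE)
      if (length(hit)) sub("^[^=]+=", "", hit[1]) else NA_character_
    }, character(1))
  }
  af_keys <- sort(setdiff(grep("^AF_", declared, value = TRUE), "AF_INHOUSE"))
  n <- nrow(fix)
  variants <- data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    gene = info_get("GENE"), transcript = info_get("TX"),
    cdna_change = info_get("CDNA"), protein_change = info_get("PROT"),
    consequence = info_get("CSQ"),
    phylop = as.numeric(info_get("PHYLOP")),
    inhouse_freq = as.numeric(info_get("AF_INHOUSE")),
    stringsAsFactors = FALSE)
  variants$consequence[is.na(variants$consequence)] <- "other"
  pop_af <- matrix(NA_real_, n, length(af_keys),
                   dimnames = list(NULL, af_keys))
  for (k in af_keys) pop_af[, k] <- as.numeric(info_get(k))

  gt_raw <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt_raw)))
    gt_raw <- matrix(gt_raw, nrow = n, dimnames = list(NULL, vcf_samples))
  gt_raw <- gt_raw[, samples, drop = FALSE]
  geno <- matrix(.gt_code(gt_raw), n, length(samples),
                 dimnames = list(NULL, samples))
  variant_set(variants, pop_af, geno)
}

.gt_code <- function(gt) {
  core <- gsub("\\|", "/", gt)
  out <- rep(NA_character_, length(core))
  out[core %in% c("0/0")] <- "hom_ref"
  out[core %in% c("0/1", "1/0")] <- "het"
  out[core %in% c("1/1")] <- "hom_alt"
  out
}

#' Write an annotated multi-sample VCF
#'
#' Emits plain-text VCF v4.2 with the annotation dialect read by
#' [read_annotated_vcf()]; the round trip preserves genotypes and all
#' annotation values.
#'
#' @param x A [variant_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotated_vcf <- function(x, path) {
  v <- x$variants
  af_keys <- colnames(x$pop_af)
  samples <- colnames(x$geno)
  hdr <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=TX,Number=1,Type=String,Description="Transcript accession">',
    '##INFO=<ID=CDNA,Number=1,Type=String,Description="cDNA change">',
    '##INFO=<ID=PROT,Number=1,Type=String,Description="Protein change (HGVS p.)">',
    '##INFO=<ID=CSQ,Number=1,Type=String,Description="Consequence class">',
    '##INFO=<ID=PHYLOP,Number=1,Type=Float,Description="phyloP conservation">',
    '##INFO=<ID=AF_INHOUSE,Number=1,Type=Float,Description="In-house cohort frequency">',
    vapply(af_keys, function(k) paste0(
      '##INFO=<ID=', k, ',Number=1,Type=Float,Description="Population allele frequency (',
      sub("^AF_", "", k), ')">'), character(1)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  fmt_num <- function(z) ifelse(is.na(z), NA, format(z, trim = TRUE, digits = 15,
                                                     scientific = FALSE))
  info <- vapply(seq_len(nrow(v)), function(i) {
    kv <- c(GENE = v$gene[i], TX = v$transcript[i], CDNA = v$cdna_change[i],
            PROT = v$protein_change[i], CSQ = v$consequence[i],
            PHYLOP = fmt_num(v$phylop[i]),
            AF_INHOUSE = fmt_num(v$inhouse_freq[i]))
    for (k in af_keys) kv[k] <- fmt_num(x$pop_af[i, k])
    kv <- kv[!is.na(kv)]
    if (!length(kv)) "." else paste(names(kv), kv, sep = "=", collapse = ";")
  }, character(1))
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1")
  gt <- matrix("./.", nrow(v), length(samples))
  ok <- !is.na(x$geno)
  gt[ok] <- gt_code[x$geno[ok]]
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", info, "GT",
                sep = "\t")
  if (length(samples))
    body <- paste(body, apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, if (nrow(v)) body), path)
  invisible(path)
}

# Three-letter -> one-letter residue codes.
.aa3to1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
             Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
             Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
             Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")

#' Parse HGVS-style protein-change notation
#'
#' Converts three-letter `p.` notation such as `"p.Val37Met"` into
#' one-letter residue codes and an integer position.
#'
#' @param text Character vector of `p.RefPosAlt` strings.
#' @return A data frame with columns `ref_aa`, `position`, `alt_aa`.
#' @examples
#' parse_protein_change("p.Val37Met")   # V 37 M
#' @export
parse_protein_change <- function(text) {
  m <- regmatches(text, regexec("^p\\.([A-Z][a-z]{2})([0-9]+)([A-Z][a-z]{2})$",
                                text))
  bad <- lengths(m) != 4
  if (any(bad))
    stop("cannot parse protein change notation: ",
         paste(text[bad], collapse = ", "))
  parts <- do.call(rbind, m)
  unknown <- !parts[, 2] %in% names(.aa3to1) | !parts[, 4] %in% names(.aa3to1)
  if (any(unknown))
    stop("unknown residue code in: ", paste(text[unknown], collapse = ", "))
  data.frame(ref_aa = unname(.aa3to1[parts[, 2]]),
             position = as.integer(parts[, 3]),
             alt_aa = unname(.aa3to1[parts[, 4]]),
             stringsAsFactors = FALSE)
}

#' Format a protein change in HGVS-style three-letter notation
#'
#' Inverse of [parse_protein_change()].
#'
#' @param ref_aa,alt_aa One-letter residue codes.
#' @param position Integer residue positions.
#' @return Character vector like `"p.Val37Met"`.
#' @export
format_protein_change <- function(ref_aa, position, alt_aa) {
  aa1to3 <- stats::setNames(names(.aa3to1), .aa3to1)
  if (any(!ref_aa %in% names(aa1to3)) || any(!alt_aa %in% names(aa1to3)))
    stop("unknown one-letter residue code")
  paste0("p.", aa1to3[ref_aa], as.integer(position), aa1to3[alt_aa])
}
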