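# Variant I/O. Records are plain data.frames with columns
#   sample, chrom, pos (1-based), ref, alt, variant_class, effect, gene
# variant_class in {"SNV","indel"}; effect in
#   {"nonsynonymous","synonymous","other","unknown"}.

MAF_NONSYN <- c("Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
                "Translation_Start_Site", "Splice_Site",
                "Frame_Shift_Del", "Frame_Shift_Ins",
                "In_Frame_Del", "In_Frame_Ins")

#' Construct a mutation record data.frame
#'
#' Low-level constructor for the record schema used throughout the
#' package; arguments are recycled to a common length.
#'
#' @param sample,chrom,pos,ref,alt,variant_class,effect,gene Record
#'   fields; see [read_variants()] for their meaning.
#' @return data.frame of mutation records.
#' @export
mutation_records <- function(sample, chrom, pos, ref, alt,
                             variant_class, effect, gene = NA_character_) {
  data.frame(sample = as.character(sample),
             chrom = as.character(chrom),
             pos = as.integer(pos),
             ref = toupper(as.character(ref)),
             alt = toupper(as.character(alt)),
             variant_class = as.character(variant_class),
             effect = as.character(effect),
             gene = as.character(gene),
             stringsAsFactors = FALSE)
}

infer_variant_class <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L &
           ref %in% DNA_BASES & alt %in% DNA_BASES, "SNV", "indel")
}

#' Read somatic variants from MAF or VCF
#'
#' Produces one record per sample-variant. Multi-allelic VCF rows are split
#' into one record per alternate allele. A variant is an SNV iff both
#' alleles are single A/C/G/T bases; everything else (including MAF "-"
#' alleles) is an indel.
#'
#' For VCF input the sample identifier is taken from `sample`; if `NULL`
#' and the VCF carries exactly one genotype column, that column name is
#' used. MAF input takes samples from `Tumor_Sample_Barcode` and maps
#' `Variant_Classification` onto effect classes (missense/nonsense/splice/
#' frameshift etc. are nonsynonymous, `Silent` is synonymous, anything else
#' is other; absent annotation is unknown).
#'
#' @param path Path to the variant file.
#' @param format `"maf"` or `"vcf"`.
#' @param sample Sample identifier for single-sample VCF input.
#' @return data.frame of mutation records (see package overview).
#' @export
read_variants <- function(path, format = c("maf", "vcf"), sample = NULL) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  rec <- switch(format,
                maf = read_variants_maf(path),
                vcf = read_variants_vcf(path, sample))
  bad <- which(rec$ref == rec$alt)
  if (length(bad))
    stop("no-op variant (ref == alt) at record ", bad[1], " of ", path)
  rec
}

read_variants_maf <- function(path) {
  maf <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
  need <- c("Chromosome", "Start_Position", "Reference_Allele",
            "Tumor_Seq_Allele2", "Tumor_Sample_Barcode")
  miss <- setdiff(need, names(maf))
  if (length(miss))
    stop("MAF is missing required columns: ", paste(miss, collapse = ", "))
  ref <- toupper(maf$Reference_Allele)
  alt <- toupper(maf$Tumor_Seq_Allele2)
  vclass <- if ("Variant_Type" %in% names(maf)) {
    vt <- toupper(maf$Variant_Type)
    ifelse(vt %in% c("SNP", "SNV"), "SNV",
           ifelse(vt %in% c("INS", "DEL", "DNP", "TNP", "ONP"),
                  ifelse(vt %in% c("INS", "DEL"), "indel",
                         infer_variant_class(ref, alt)),
                  infer_variant_class(ref, alt)))
  } else infer_variant_class(ref, alt)
  effect <- if ("Variant_Classification" %in% names(maf)) {
    vc <- maf$Variant_Classification
    ifelse(vc %in% MAF_NONSYN, "nonsynonymous",
           ifelse(vc == "Silent", "synonymous",
                  ifelse(is.na(vc) | vc == "", "unknown", "other")))
  } else "unknown"
  gene <- if ("Hugo_Symbol" %in% names(maf)) maf$Hugo_Symbol else NA_character_
  bad <- which(is.na(suppressWarnings(as.integer(maf$Start_Position))))
  if (length(bad))
    stop("unparseable Start_Position in MAF data row ", bad[1])
  mutation_records(maf$Tumor_Sample_Barcode, maf$Chromosome,
                       maf$Start_Position, ref, alt, vclass, effect, gene)
}

read_variants_vcf <- function(path, sample) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- t(fix)  # single-row VCFs drop to a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (is.null(sample)) {
    gt_samples <- colnames(v@gt)
    gt_samples <- gt_samples[gt_samples != "FORMAT"]
    if (length(gt_samples) == 1L) sample <- gt_samples
    else stop("VCF sample ambiguous: pass `sample=` (found ",
              length(gt_samples), " genotype columns)")
  }
  pos <- suppressWarnings(as.integer(fix$POS))
  bad <- which(is.na(pos) | is.na(fix$REF) | is.na(fix$ALT) | fix$ALT == ".")
  if (length(bad))
    stop("unparseable VCF data row ", bad[1], " in ", path)
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n <- lengths(alts)
  idx <- rep.int(seq_along(n), n)
  ref <- toupper(fix$REF[idx])
  alt <- toupper(unlist(alts))
  info <- fix$INFO[idx]
  gene <- vcf_info_field(info, "GENE")
  effect <- vcf_info_field(info, "EFFECT")
  effect[is.na(effect)] <- "unknown"
  effect[!effect %in% c("nonsynonymous", "synonymous", "other")] <- "unknown"
  mutation_records(sample, fix$CHROM[idx], pos[idx], ref, alt,
                       infer_variant_class(ref, alt), effect, gene)
}

vcf_info_field <- function(info, key) {
  if (is.null(info)) return(rep(NA_character_, length(info)))
  m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]+"), info))
  out <- rep(NA_character_, length(info))
  hit <- grepl(paste0("(^|;)", key, "="), info)
  out[hit] <- sub(paste0("^;?", key, "="), "", m)
  out
}

#' Check that record reference alleles match the genome
#'
#' @param records Mutation record data.frame.
#' @param genome Named character genome vector.
#' @return Logical vector, `TRUE` where the SNV reference base equals the
#'   genome base at that position (non-SNVs give `NA`).
#' @export
ref_matches_genome <- function(records, genome) {
  validate_genome(genome)
  out <- rep(NA, nrow(records))
  snv <- records$variant_class == "SNV"
  for (chrom in unique(records$chrom[snv])) {
    i <- which(snv & records$chrom == chrom)
    s <- genome[[chrom]]
    if (is.null(s)) { out[i] <- FALSE; next }
    ok <- records$pos[i] >= 1 & records$pos[i] <= nchar(s)
    base <- rep(NA_character_, length(i))
    base[ok] <- substring(s, records$pos[i][ok], records$pos[i][ok])
    out[i] <- !is.na(base) & base == records$ref[i]
  }
  out
}
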