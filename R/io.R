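#' @include replication.R
NULL

#' Write a genotype panel as a minimal VCF (GT and DS fields)
#'
#' Hard-called GT is derived by rounding the dosage; the DS field keeps the
#' dosage itself.  Missing dosages become `./.`.
#'
#' @param panel a [GenotypePanel-class].
#' @param path output file (`.vcf`, uncompressed).
#' @export
writeGenotypesVcf <- function(panel, path) {
  s <- snpInfo(panel); d <- dosages(panel)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">"),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(d)), collapse = "\t"), con)
  gtOf <- function(x) {
    ifelse(is.na(x), "./.",
           c("0/0", "0/1", "1/1")[pmin(pmax(round(x), 0), 2) + 1])
  }
  for (j in seq_len(nrow(s))) {
    calls <- paste0(gtOf(d[, j]), ":",
                    ifelse(is.na(d[, j]), ".", format(d[, j], digits = 6)))
    writeLines(paste(c(s$chrom[j], s$pos[j], s$snp_id[j], s$ref[j], s$alt[j],
                       ".", "PASS", ".", "GT:DS", calls), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a VCF into a genotype panel
#'
#' Uses the DS field when present, otherwise converts GT to a 0/1/2 dosage.
#'
#' @param path VCF file.
#' @return a [GenotypePanel-class].
#' @export
readGenotypesVcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  hasDs <- "DS" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID
  if (hasDs) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    ds[] <- vapply(gsub("\\|", "/", gt), function(g) {
      if (is.na(g) || g == "./.") NA_real_
      else sum(as.numeric(strsplit(g, "/")[[1]]))
    }, numeric(1))
  }
  dosage <- t(ds)
  snps <- data.frame(snp_id = fix$ID, chrom = fix$CHROM,
                     pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                     stringsAsFactors = FALSE)
  genotypePanel(dosage, snps)
}

#' Write/read dosage matrices and study tables as TSV
#'
#' `writeGenotypesTsv` writes the SNP table and the dosage matrix
#' (individuals x SNPs); `readGenotypesTsv` reads them back.
#'
#' @param panel a [GenotypePanel-class].
#' @param prefix file prefix; `<prefix>_dosage.tsv` and `<prefix>_snps.tsv`
#'   are written.
#' @export
writeGenotypesTsv <- function(panel, prefix) {
  d <- data.table::as.data.table(dosages(panel), keep.rownames = "individual_id")
  data.table::fwrite(d, paste0(prefix, "_dosage.tsv"), sep = "\t")
  data.table::fwrite(snpInfo(panel), paste0(prefix, "_snps.tsv"), sep = "\t")
  invisible(prefix)
}

#' @rdname writeGenotypesTsv
#' @export
readGenotypesTsv <- function(prefix) {
  d <- data.table::fread(paste0(prefix, "_dosage.tsv"), sep = "\t",
                         data.table = FALSE)
  snps <- data.table::fread(paste0(prefix, "_snps.tsv"), sep = "\t",
                            data.table = FALSE)
  snps$chrom <- as.character(snps$chrom)
  dm <- as.matrix(d[, -1, drop = FALSE])
  rownames(dm) <- d[[1]]
  genotypePanel(dm, snps)
}

#' Write an expression study to a directory of TSV files
#'
#' One samples x genes matrix per condition, a sample sheet, and a BED-like
#' gene annotation (0-based half-open TSS interval, columns chrom, start,
#' end, gene_id).
#'
#' @param study an [ExpressionStudy-class].
#' @param dir output directory (created if needed).
#' @export
writeStudyTsv <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cond in unique(sampleSheet(study)$condition)) {
    m <- exprMatrix(study, cond)
    dt <- data.table::as.data.table(m, keep.rownames = "sample_id")
    data.table::fwrite(dt, file.path(dir, paste0("expr_", cond, ".tsv")),
                       sep = "\t")
  }
  data.table::fwrite(sampleSheet(study), file.path(dir, "samples.tsv"),
                     sep = "\t")
  g <- geneInfo(study)
  bed <- data.frame(chrom = g$chrom, start = g$tss - 1L, end = g$tss,
                    gene_id = g$gene_id)
  data.table::fwrite(bed, file.path(dir, "genes.bed"), sep = "\t",
                     col.names = FALSE)
  invisible(dir)
}

#' Write GWAS summary statistics as TSV
#'
#' @param gwas a GWAS summary data.frame.
#' @param path output file.
#' @export
writeGwasTsv <- function(gwas, path) {
  data.table::fwrite(gwas, path, sep = "\t")
  invisible(path)
}

# column synonyms tolerated by the GWAS reader
.gwasSynonyms <- list(
  snp_id = c("snp_id", "snp", "rsid", "variant_id", "id", "markername"),
  chrom = c("chrom", "chr", "chromosome"),
  pos = c("pos", "bp", "position", "base_pair_location"),
  effect_allele = c("effect_allele", "ea", "a1", "alt", "allele1"),
  other_allele = c("other_allele", "oa", "a2", "ref", "allele2", "nea"),
  beta = c("beta", "b", "effect", "beta_hat"),
  se = c("se", "standard_error", "stderr"),
  p = c("p", "pval", "p_value", "pvalue"))

#' Read GWAS summary statistics, tolerating column synonyms
#'
#' Maps common header variants (e.g. `rsid`, `a1`/`a2`, `pval`) onto the
#' canonical columns `snp_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `beta`, `se`, `p`.
#'
#' @param path TSV file.
#' @param mapping optional named list overriding the synonym table
#'   (canonical name -> column name in the file).
#' @return data.frame with canonical columns.
#' @export
readGwasTsv <- function(path, mapping = NULL) {
  g <- data.table::fread(path, sep = "\t", data.table = FALSE)
  nmLower <- tolower(names(g))
  out <- list()
  for (canon in names(.gwasSynonyms)) {
    colName <- if (!is.null(mapping) && canon %in% names(mapping))
      tolower(mapping[[canon]]) else {
        hits <- which(nmLower %in% .gwasSynonyms[[canon]])
        if (length(hits)) nmLower[hits[1]] else NA_character_
      }
    if (!is.na(colName) && colName %in% nmLower)
      out[[canon]] <- g[[which(nmLower == colName)[1]]]
  }
  need <- c("snp_id", "effect_allele", "other_allele", "beta", "se", "p")
  miss <- setdiff(need, names(out))
  if (length(miss))
    stop("GWAS file lacks required column(s): ", paste(miss, collapse = ", "))
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  if (!is.null(out$chrom)) out$chrom <- as.character(out$chrom)
  out
}

#' Write/read the planted truth as JSON
#'
#' @param truth a [TruthTable-class].
#' @param path JSON file.
#' @export
writeTruthJson <- function(truth, path) {
  jsonlite::write_json(
    list(cis = cisTruth(truth), trans = transTruth(truth),
         gwas_loci = gwasLociTruth(truth),
         causal_genes = causalGeneTruth(truth)),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeTruthJson
#' @export
readTruthJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fix <- function(df, empty) {
    if (is.null(df) || (is.data.frame(df) && nrow(df) == 0) ||
        length(df) == 0) empty else as.data.frame(df)
  }
  truthTable(cis = fix(x$cis, emptyCisTruth()),
             trans = fix(x$trans, emptyTransTruth()),
             gwasLoci = fix(x$gwas_loci, emptyGwasLociTruth()),
             causalGenes = fix(x$causal_genes, emptyCausalGeneTruth()))
}

#' Validate study input files
#'
#' Conformance checks for the on-disk formats: VCF structure (column count
#' per row), positive 1-based positions, allele-column sanity, and gene
#' annotation arithmetic (a negative or zero TSS after BED conversion flags
#' a 0/1-based mix-up).  Malformed rows are listed with line numbers.
#'
#' @param vcf optional VCF path.
#' @param genesBed optional BED-like gene annotation path.
#' @param gwas optional GWAS TSV path.
#' @return list with `ok` (logical) and `problems` (data.frame file, line,
#'   message).
#' @export
validateStudyFiles <- function(vcf = NULL, genesBed = NULL, gwas = NULL) {
  problems <- list()
  note <- function(file, line, msg)
    problems[[length(problems) + 1L]] <<- data.frame(
      file = file, line = line, message = msg, stringsAsFactors = FALSE)
  if (!is.null(vcf)) {
    lines <- readLines(vcf)
    body <- which(!startsWith(lines, "#"))
    hdr <- which(startsWith(lines, "#CHROM"))
    if (!length(hdr)) note(vcf, NA, "missing #CHROM header") else {
      nCols <- length(strsplit(lines[hdr], "\t")[[1]])
      for (i in body) {
        f <- strsplit(lines[i], "\t")[[1]]
        if (length(f) != nCols) {
          note(vcf, i, sprintf("expected %d columns, found %d", nCols, length(f)))
          next
        }
        if (is.na(suppressWarnings(as.integer(f[2]))) ||
            as.integer(f[2]) <= 0)
          note(vcf, i, "position must be a positive 1-based integer")
        if (!grepl("^[ACGT]+$", f[4]) || !grepl("^[ACGT,]+$", f[5]))
          note(vcf, i, "invalid REF/ALT alleles")
      }
    }
  }
  if (!is.null(genesBed)) {
    bed <- read.delim(genesBed, header = FALSE, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(bed))) {
      if (bed[i, 2] < 0 || bed[i, 3] <= bed[i, 2])
        note(genesBed, i, "invalid 0-based half-open interval (start/end)")
      if (bed[i, 3] - bed[i, 2] != 1)
        note(genesBed, i, "TSS interval must have width 1")
    }
    if (any(bed[, 2] < 0))
      note(genesBed, NA, "negative start: possible 0/1-based convention mix-up")
  }
  if (!is.null(gwas)) {
    res <- tryCatch(readGwasTsv(gwas), error = function(e) conditionMessage(e))
    if (is.character(res)) note(gwas, NA, res)
    else if (any(res$se <= 0, na.rm = TRUE))
      note(gwas, NA, "non-positive standard errors")
  }
  problems <- if (length(problems)) do.call(rbind, problems) else
    data.frame(file = character(), line = integer(), message = character(),
               stringsAsFactors = FALSE)
  list(ok = nrow(problems) == 0L, problems = problems)
}
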