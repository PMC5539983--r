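#' Read genotypes from VCF or PLINK files
#'
#' For VCF input the `DS` (dosage) FORMAT field is preferred when present;
#' otherwise dosages are alt-allele counts from `GT`. PLINK input expects the
#' binary trio `<prefix>.bed/.bim/.fam` (SNP-major bed).
#'
#' @param path file path (VCF) or prefix (PLINK trio; a trailing `.bed` is
#'   stripped).
#' @param format `"vcf"` or `"plink"`. Guessed from the file name by default.
#' @return a `genotype_matrix`.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "plink")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "plink"
  }
  switch(format, vcf = read_vcf(path), plink = read_plink(path))
}

#' @rdname read_genotypes
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ids <- fix[, "ID"]
  blank <- is.na(ids) | ids == "."
  ids[blank] <- paste0(fix[blank, "CHROM"], "_", fix[blank, "POS"])
  if (anyDuplicated(ids)) stop("duplicated variant id in VCF: ",
                               ids[duplicated(ids)][1])
  variants <- data.frame(id = ids,
                         chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         ref = fix[, "REF"],
                         alt = fix[, "ALT"],
                         stringsAsFactors = FALSE)
  fmt_keys <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)))
  if ("DS" %in% fmt_keys) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else if ("GT" %in% fmt_keys) {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, 2, gt_to_dosage)
    if (is.null(dim(ds))) ds <- matrix(ds, nrow = 1, dimnames = dimnames(gt))
  } else {
    stop("VCF has neither GT nor DS in FORMAT")
  }
  # vcfR returns variants x samples; transpose to individuals x variants
  genotype_matrix(t(ds), variants, colnames(v@gt)[-1])
}

gt_to_dosage <- function(gt) {
  alleles <- strsplit(sub(":.*", "", gt), "[/|]")
  vapply(alleles, function(a) {
    if (length(a) == 0 || any(a == ".")) return(NA_real_)
    sum(a != "0")
  }, numeric(1))
}

#' Write genotypes as a plain-text VCF
#'
#' Emits a minimal VCFv4.2 file with a `GT` field and, when any dosage is
#' fractional, a `DS` field carrying the dosage (GT then holds the rounded
#' genotype). Missing dosages become `./.`.
#'
#' @param g a `genotype_matrix`.
#' @param path output path (plain text; not compressed).
#' @param dosage_field write the DS field even if all dosages are integral.
#' @return the path, invisibly.
#' @export
write_vcf <- function(g, path, dosage_field = NULL) {
  dos <- g$dosages
  fractional <- any(abs(dos - round(dos)) > 1e-9, na.rm = TRUE)
  if (is.null(dosage_field)) dosage_field <- fractional
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=grmpart",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'), con)
  if (dosage_field) {
    writeLines('##FORMAT=<ID=DS,Number=1,Type=Float,Description="Dosage">', con)
  }
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", g$individual_ids), collapse = "\t"), con)
  fmt <- if (dosage_field) "GT:DS" else "GT"
  gt_codes <- c("0/0", "0/1", "1/1")
  for (j in seq_len(n_variants(g))) {
    d <- dos[, j]
    r <- pmin(pmax(round(d), 0), 2)
    gt <- ifelse(is.na(d), "./.", gt_codes[r + 1])
    cell <- if (dosage_field) {
      ifelse(is.na(d), "./.:.", paste0(gt, ":", format_num(d)))
    } else gt
    vr <- g$variants[j, ]
    writeLines(paste(c(vr$chrom, vr$pos, vr$id, vr$ref, vr$alt, ".", "PASS",
                       ".", fmt, cell), collapse = "\t"), con)
  }
  invisible(path)
}

format_num <- function(x) {
  out <- formatC(x, format = "g", digits = 15)
  gsub(" ", "", out)
}

#' Read a PLINK bed/bim/fam trio
#'
#' SNP-major binary bed files only (magic bytes 0x6c 0x1b 0x01). Dosage is
#' the alt (A1) allele count; PLINK's missing code becomes `NA`.
#'
#' @param prefix path prefix; `.bed/.bim/.fam` are appended (a supplied
#'   `.bed` suffix is stripped).
#' @return a `genotype_matrix`.
#' @export
read_plink <- function(prefix) {
  prefix <- sub("\\.bed$", "", prefix)
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("no such file: ", f)

  bim_df <- utils::read.table(bim, stringsAsFactors = FALSE,
                              col.names = c("chrom", "id", "cm", "pos", "a1", "a2"))
  fam_df <- utils::read.table(fam, stringsAsFactors = FALSE,
                              col.names = c("fid", "iid", "sire", "dam", "sex", "pheno"))
  n <- nrow(fam_df)
  m <- nrow(bim_df)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("not a PLINK bed file: ", bed)
  }
  if (raw[3] != as.raw(0x01)) stop("only SNP-major bed files are supported")
  bytes_per_snp <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != bytes_per_snp * m) {
    stop("bed file size inconsistent with bim/fam dimensions")
  }
  # two-bit codes per individual: 00=hom A1(2), 01=missing, 10=het(1), 11=hom A2(0)
  lut <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)
  ints <- as.integer(body)
  codes <- rbind(ints %% 4L, (ints %/% 4L) %% 4L,
                 (ints %/% 16L) %% 4L, (ints %/% 64L) %% 4L)
  dim(codes) <- c(4L * bytes_per_snp, m)
  dos <- matrix(lut[codes[seq_len(n), , drop = FALSE] + 1L], nrow = n, ncol = m)
  variants <- data.frame(id = bim_df$id, chrom = as.character(bim_df$chrom),
                         pos = bim_df$pos, ref = bim_df$a2, alt = bim_df$a1,
                         stringsAsFactors = FALSE)
  ord <- order(variants$chrom, variants$pos)
  g <- genotype_matrix(dos[, ord, drop = FALSE], variants[ord, , drop = FALSE],
                       as.character(fam_df$iid))
  g
}

#' Write a PLINK bed/bim/fam trio
#'
#' Fractional dosages are rounded to hard genotype calls (bed cannot carry
#' dosage).
#'
#' @param g a `genotype_matrix`.
#' @param prefix output path prefix.
#' @return the prefix, invisibly.
#' @export
write_plink <- function(g, prefix) {
  n <- n_individuals(g)
  m <- n_variants(g)
  bim <- data.frame(chrom = g$variants$chrom, id = g$variants$id, cm = 0,
                    pos = g$variants$pos, a1 = g$variants$alt, a2 = g$variants$ref)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = g$individual_ids, iid = g$individual_ids,
                    sire = 0, dam = 0, sex = 0, pheno = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  code_map <- c(`0` = 3L, `1` = 2L, `2` = 0L)  # dosage -> two-bit code
  bytes_per_snp <- ceiling(n / 4)
  out <- raw(3 + bytes_per_snp * m)
  out[1:3] <- as.raw(c(0x6c, 0x1b, 0x01))
  pad <- 4L * bytes_per_snp - n
  for (j in seq_len(m)) {
    d <- round(g$dosages[, j])
    codes <- ifelse(is.na(d), 1L, code_map[as.character(d)])
    codes <- c(codes, rep(0L, pad))
    dim(codes) <- c(4L, bytes_per_snp)
    byte_vals <- codes[1, ] + 4L * codes[2, ] + 16L * codes[3, ] + 64L * codes[4, ]
    out[3 + (j - 1) * bytes_per_snp + seq_len(bytes_per_snp)] <- as.raw(byte_vals)
  }
  writeBin(out, paste0(prefix, ".bed"))
  invisible(prefix)
}

#' Read / write a phenotype table
#'
#' Tab-separated table with columns `id`, `trait`, `drp`, `reliability`.
#'
#' @param path file path.
#' @return data.frame with those columns.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  needed <- c("id", "trait", "drp", "reliability")
  if (!all(needed %in% names(df))) {
    stop("phenotype table needs columns: ", paste(needed, collapse = ", "))
  }
  df$id <- as.character(df$id)
  if (any(df$reliability <= 0 | df$reliability > 1)) {
    stop("reliabilities must lie in (0, 1]")
  }
  df
}

#' @rdname read_phenotypes
#' @param phenotypes data.frame as returned by [simulate_phenotypes()].
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a pedigree
#'
#' CSV with columns `id`, `sire`, `dam`; `0` (or empty) marks an unknown
#' parent. Records must be topologically ordered (parents before offspring).
#'
#' @param path file path.
#' @return a `pedigree` data.frame (see [simulate_pedigree()]).
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("id", "sire", "dam") %in% names(df))) {
    stop("pedigree needs columns id, sire, dam")
  }
  df$sire[df$sire %in% c("", "0", "NA")] <- NA
  df$dam[df$dam %in% c("", "0", "NA")] <- NA
  as_pedigree(df)
}

#' @rdname read_pedigree
#' @param ped a `pedigree`.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(id = ped$id,
                    sire = ifelse(is.na(ped$sire), "0", ped$sire),
                    dam = ifelse(is.na(ped$dam), "0", ped$dam))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write relationship matrices
#'
#' Two on-disk forms: `"text"` is a full symmetric matrix as tab-separated
#' text with an id header row; `"binary"` is the row-major lower triangle
#' (including the diagonal) as little-endian 4-byte floats, with ids in a
#' `<path>.ids` sidecar file.
#'
#' @param K a `relationship_matrix`.
#' @param path output path.
#' @param format `"text"` or `"binary"`.
#' @return the path, invisibly (`write`); a `relationship_matrix` (`read`).
#' @export
write_relmat <- function(K, path, format = c("text", "binary")) {
  format <- match.arg(format)
  if (format == "text") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("id", K$ids), collapse = "\t"), con)
    for (i in seq_along(K$ids)) {
      writeLines(paste(c(K$ids[i], format_num(K$matrix[i, ])), collapse = "\t"), con)
    }
  } else {
    n <- length(K$ids)
    lower <- K$matrix[lower.tri(K$matrix, diag = TRUE)]
    # lower.tri is column-major; reorder to row-major lower triangle
    idx <- which(lower.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
    ord <- order(idx[, "row"], idx[, "col"])
    writeBin(as.numeric(lower[ord]), path, size = 4, endian = "little")
    writeLines(K$ids, paste0(path, ".ids"))
  }
  invisible(path)
}

#' @rdname write_relmat
#' @param kind the `kind` tag to attach on read.
#' @export
read_relmat <- function(path, format = c("text", "binary"), kind = "custom") {
  format <- match.arg(format)
  if (format == "text") {
    lines <- readLines(path)
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    ids <- header[-1]
    n <- length(ids)
    mat <- matrix(0, n, n)
    for (i in seq_len(n)) {
      f <- strsplit(lines[i + 1], "\t", fixed = TRUE)[[1]]
      mat[i, ] <- as.numeric(f[-1])
    }
  } else {
    ids <- readLines(paste0(path, ".ids"))
    n <- length(ids)
    vals <- readBin(path, "numeric", n = n * (n + 1) / 2, size = 4,
                    endian = "little")
    mat <- matrix(0, n, n)
    k <- 1
    for (i in seq_len(n)) {
      mat[i, 1:i] <- vals[k:(k + i - 1)]
      k <- k + i
    }
    mat <- mat + t(mat) - diag(diag(mat))
  }
  relationship_matrix(mat, ids, kind = kind)
}
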