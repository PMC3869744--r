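# Genotype and panel table I/O.
#
# Primary on-disk format is a tab-separated dosage table (header:
# subject_id then SNP ids; entries 0/1/2 risk-allele counts, missing NA).
# A VCF dialect is also accepted: dosages are derived from the GT field
# against the panel's risk allele; any half-missing genotype (./., 0/.)
# is treated as missing.

#' Read a risk-allele dosage matrix
#'
#' @param path file path
#' @param dialect \code{"tsv"} (default) or \code{"vcf"}
#' @param panel for the VCF dialect, a panel data.frame (see
#'   \code{\link{read_panel}}) giving each SNP's risk allele
#' @return numeric matrix (subjects x SNPs) of dosages in \{0,1,2,NA\}
#' @export
read_genotypes <- function(path, dialect = c("tsv", "vcf"), panel = NULL) {
  dialect <- match.arg(dialect)
  assert_that(file.exists(path), paste0("genotype file not found: ", path))
  if (dialect == "tsv") read_genotypes_tsv(path) else read_genotypes_vcf(path, panel)
}

read_genotypes_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  assert_that(names(tab)[1] == "subject_id",
              "dosage table must start with a subject_id column")
  ids <- tab$subject_id
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    line <- which(duplicated(ids))[1] + 1L  # +1 for header
    abort_validation(sprintf("duplicate subject id '%s' at line %d", dup[1], line))
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  bad <- which(!(is.na(m) | m %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad)) {
    abort_validation(sprintf("invalid dosage %s at line %d (subject %s, SNP %s)",
                             format(m[bad[1, , drop = FALSE]]),
                             bad[1, 1] + 1L, ids[bad[1, 1]],
                             colnames(m)[bad[1, 2]]))
  }
  rownames(m) <- ids
  m
}

read_genotypes_vcf <- function(path, panel) {
  assert_that(!is.null(panel), "VCF dialect requires a SNP panel")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- ids %in% panel$id
  gt <- gt[keep, , drop = FALSE]
  ids <- ids[keep]; ref <- ref[keep]; alt <- alt[keep]
  out <- matrix(NA_real_, nrow = ncol(gt), ncol = nrow(gt),
                dimnames = list(colnames(gt), ids))
  for (i in seq_along(ids)) {
    risk <- panel$risk_allele[match(ids[i], panel$id)]
    if (!risk %in% c(ref[i], alt[i])) {
      abort_validation(sprintf("risk allele %s of %s matches neither REF nor ALT",
                               risk, ids[i]))
    }
    risk_code <- if (risk == ref[i]) "0" else "1"
    alleles <- strsplit(gsub("\\|", "/", gt[i, ]), "/", fixed = TRUE)
    out[, i] <- vapply(alleles, function(a) {
      if (length(a) != 2L || any(a == ".") || any(is.na(a))) return(NA_real_)
      sum(a == risk_code)
    }, numeric(1))
  }
  out
}

#' Write a dosage matrix as a tab-separated table
#'
#' @param matrix numeric dosage matrix with subject row names
#' @param path output path
#' @export
write_genotypes <- function(matrix, path) {
  df <- data.frame(subject_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a SNP panel table
#'
#' Tab-separated with columns \code{id}, \code{chr}, \code{risk_allele},
#' \code{nonrisk_allele} and optional \code{beta}, \code{weight}.
#'
#' @param path file path
#' @return data.frame
#' @export
read_panel <- function(path) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_that(all(c("id", "risk_allele", "nonrisk_allele") %in% names(p)),
              "panel must have id, risk_allele, nonrisk_allele columns")
  assert_that(!anyDuplicated(p$id), "panel SNP ids must be unique")
  assert_that(all(p$risk_allele != p$nonrisk_allele),
              "risk and non-risk alleles must differ")
  p
}

#' @rdname read_panel
#' @param panel panel data.frame
#' @export
write_panel <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
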