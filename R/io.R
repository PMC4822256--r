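#' Write and read trait matrices as (gzipped) TSV
#'
#' Probes x individuals layout with a `probe` id column; `.gz` paths are
#' compressed transparently.
#'
#' @param trait A `trait_matrix`.
#' @param path Output path (`.tsv` or `.tsv.gz`).
#' @return `path`, invisibly.
#' @export
write_trait_tsv <- function(trait, path) {
  df <- data.frame(probe = rownames(trait$values), trait$values,
                   check.names = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trait_tsv
#' @param kind,annot Passed to [new_trait_matrix()] when reading.
#' @export
read_trait_tsv <- function(path, kind = "expression", annot = NULL) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  new_trait_matrix(m, annot, kind)
}

#' Write probe annotations as BED
#'
#' 0-based half-open intervals (`start - 1`, `end`), one line per probe with
#' the probe id in the name column.
#'
#' @param annot Tibble with `probe`, `chrom`, `start`, `end` (1-based).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_bed <- function(annot, path) {
  bed <- data.frame(chrom = annot$chrom, start = annot$start - 1,
                    end = annot$end, name = annot$probe)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a pedigree as a PLINK-style .fam-like TSV
#'
#' Columns: family, id, father, mother, sex (1 = M, 2 = F), role.
#'
#' @param pedigree Pedigree tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree_fam <- function(pedigree, path) {
  fam <- data.frame(
    family = pedigree$family, id = pedigree$id,
    father = ifelse(is.na(pedigree$father), "0", pedigree$father),
    mother = ifelse(is.na(pedigree$mother), "0", pedigree$mother),
    sex = ifelse(pedigree$sex == "M", 1L, 2L),
    role = pedigree$role
  )
  write.table(fam, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a dosage matrix as (gzipped) TSV
#'
#' SNPs x individuals with `snp`, `chrom`, `pos` leading columns.
#'
#' @param genotypes A `genotype_matrix`.
#' @param path Output path (`.tsv` or `.tsv.gz`).
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  df <- data.frame(genotypes$snps[, c("snp", "chrom", "pos")],
                   t(genotypes$dosage), check.names = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a truth record as structured JSON
#'
#' Serializes the per-probe truth table, the planted pair table and the
#' generator settings (matrix-valued fields such as per-probe genetic values
#' are omitted; they are reproducible from the seed).
#'
#' @param truth A `truth_record`.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  obj <- list(
    probes = truth$probes,
    pairs = truth$pairs[, setdiff(names(truth$pairs), "shared_snps")],
    spec = unclass(truth$spec)
  )
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
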