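# Readers/writers for the plain-text formats the pipeline touches (GMT,
# expression TSV, clinical TSV, MAF column subset, SEG, BED4). Downstream
# modules only ever see the in-memory types these produce. All coordinates
# are converted to 1-based inclusive on the way in; writers emit TSV with a
# header and a deterministic column order, numerics at full precision so
# write/read round-trips are exact.

#' Construct a gene set
#'
#' @param name non-empty set name.
#' @param genes character vector of gene symbols; duplicates are collapsed
#'   (first occurrence kept) with a warning.
#' @return object of class `GeneSet` with fields `name`, `genes`.
#' @export
gene_set <- function(name, genes) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("gene set name must be a non-empty string")
  genes <- as.character(genes)
  if (anyDuplicated(genes)) {
    warning("gene set '", name, "': duplicate symbols collapsed: ",
            paste(unique(genes[duplicated(genes)]), collapse = ", "))
    genes <- genes[!duplicated(genes)]
  }
  structure(list(name = name, genes = genes), class = "GeneSet")
}

#' @export
print.GeneSet <- function(x, ...) {
  cat(sprintf("GeneSet '%s' (%d genes)\n", x$name, length(x$genes)))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' GMT lines are tab-separated: set name, description (discarded), then one
#' gene symbol per field.
#'
#' @param path path to a GMT file.
#' @return list of [gene_set()] objects, one per line, in file order.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop("malformed GMT line ", i, " in '", path, "': fewer than 3 fields")
    out[[i]] <- gene_set(fields[1], fields[-(1:2)])
  }
  out
}

#' Write gene sets to a GMT file
#' @param sets list of `GeneSet` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$name, "na", s$genes), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

# full-precision numeric formatting so TSV round-trips are exact
.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

.write_tsv <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) {
    if (is.double(df2[[j]])) df2[[j]] <- .fmt_num(df2[[j]])
  }
  utils::write.table(df2, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' First column gene ids, header row sample ids, numeric body. Duplicate
#' gene rows are resolved by keeping the row with the highest mean (a
#' message reports which were dropped); duplicate sample ids are an error.
#'
#' @param path path to TSV.
#' @param scale_tag declared scale of the stored values (see
#'   [expression_matrix()]).
#' @return an `ExpressionMatrix`; sample order follows the file.
#' @export
read_expression_tsv <- function(path, scale_tag = "tpm") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("expression TSV needs a gene column plus >=1 sample")
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample id in '", path, "': ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  genes <- df[[1]]
  body <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(vals) & !(body %in% c("NA", "")), arr.ind = TRUE)
  nab <- which(body %in% c("NA", ""), arr.ind = TRUE)
  bad <- rbind(bad, nab)
  if (nrow(bad))
    stop(sprintf("non-numeric cell in '%s' at gene row %d, sample '%s'",
                 path, bad[1, 1], samples[bad[1, 2]]))
  dimnames(vals) <- list(genes, samples)
  if (anyDuplicated(genes)) {
    means <- rowMeans(vals)
    ord <- order(-means)         # highest-mean row first, then first-wins
    keep <- ord[!duplicated(genes[ord])]
    keep <- sort(keep)
    message("read_expression_tsv: ", nrow(vals) - length(keep),
            " duplicate gene row(s) dropped, keeping highest-mean rows")
    vals <- vals[keep, , drop = FALSE]
  }
  expression_matrix(vals, scale_tag)
}

#' Write an ExpressionMatrix to TSV
#' @param x an `ExpressionMatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  df <- data.frame(gene_id = gene_ids(x), stringsAsFactors = FALSE)
  vals <- x$values
  for (s in sample_ids(x)) df[[s]] <- vals[, s]
  .write_tsv(df, path)
}

#' Read a clinical table from TSV
#'
#' Required columns: `sample_id`, `os_months`, `os_event`. Optional:
#' `purity` (fraction in \[0,1\], NA allowed) and any categorical covariates
#' (`stage`, `grade`, `age`, ...), which are carried through untouched.
#'
#' @param path path to TSV.
#' @return a `data.frame` with class `ClinicalTable` prepended.
#' @export
read_clinical_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  clinical_table(df)
}

#' Validate a clinical data.frame
#' @param df data.frame with at least sample_id, os_months, os_event.
#' @return the validated data.frame, classed `ClinicalTable`.
#' @export
clinical_table <- function(df) {
  req <- c("sample_id", "os_months", "os_event")
  miss <- setdiff(req, colnames(df))
  if (length(miss)) stop("clinical table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in clinical table")
  if (any(df$os_months < 0, na.rm = TRUE)) stop("negative os_months")
  if (!all(df$os_event %in% c(0, 1)))
    stop("os_event must be 0/1")
  if ("purity" %in% colnames(df) &&
      any(df$purity < 0 | df$purity > 1, na.rm = TRUE))
    stop("purity must lie in [0, 1]")
  class(df) <- unique(c("ClinicalTable", class(df)))
  df
}

#' Write a clinical table to TSV
#' @param df a `ClinicalTable`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical_tsv <- function(df, path) .write_tsv(df, path)

#' Read a minimal MAF (somatic mutations)
#'
#' Requires columns `Hugo_Symbol`, `Tumor_Sample_Barcode`, `Variant_Type`;
#' `Chromosome`/`Start_Position` are carried when present. Variant types
#' SNP/DNP/TNP map to `SNV`, INS/DEL to `INDEL`; anything else is dropped
#' with a message giving the count.
#'
#' @param path path to a tab-separated MAF (comment lines starting `#`
#'   are skipped).
#' @return data.frame `MutationTable` with columns
#'   `sample_id`, `gene`, `variant_class`, `chrom`, `pos`.
#' @export
read_maf_minimal <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  req <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Type")
  miss <- setdiff(req, colnames(df))
  if (length(miss)) stop("MAF missing required column(s): ",
                         paste(miss, collapse = ", "))
  map <- c(SNP = "SNV", DNP = "SNV", TNP = "SNV", INS = "INDEL", DEL = "INDEL")
  cls <- unname(map[df$Variant_Type])
  n_drop <- sum(is.na(cls))
  if (n_drop) message("read_maf_minimal: dropped ", n_drop,
                      " record(s) with unsupported Variant_Type")
  keep <- !is.na(cls)
  mutation_table(data.frame(
    sample_id = df$Tumor_Sample_Barcode[keep],
    gene = df$Hugo_Symbol[keep],
    variant_class = cls[keep],
    chrom = if ("Chromosome" %in% colnames(df))
      as.character(df$Chromosome[keep]) else NA_character_,
    pos = if ("Start_Position" %in% colnames(df))
      as.numeric(df$Start_Position[keep]) else NA_real_,
    stringsAsFactors = FALSE))
}

#' Validate a mutation record table
#' @param df data.frame with sample_id, gene, variant_class, chrom, pos.
#' @return the validated data.frame, classed `MutationTable`.
#' @export
mutation_table <- function(df) {
  req <- c("sample_id", "gene", "variant_class")
  miss <- setdiff(req, colnames(df))
  if (length(miss)) stop("mutation table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(df$variant_class %in% c("SNV", "INDEL")))
    stop("variant_class restricted to SNV/INDEL")
  class(df) <- unique(c("MutationTable", class(df)))
  df
}

#' Write a mutation table as a minimal MAF
#' @param df a `MutationTable`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_maf_minimal <- function(df, path) {
  inv <- c(SNV = "SNP", INDEL = "DEL")
  out <- data.frame(Hugo_Symbol = df$gene,
                    Tumor_Sample_Barcode = df$sample_id,
                    Variant_Type = unname(inv[df$variant_class]),
                    Chromosome = df$chrom,
                    Start_Position = df$pos,
                    stringsAsFactors = FALSE)
  .write_tsv(out, path)
}

#' Read copy-number segments (SEG format)
#'
#' Standard SEG columns: ID, chrom, loc.start, loc.end, num.mark, seg.mean.
#' Coordinates are taken as 1-based inclusive (SEG convention). A missing
#' num.mark column yields `num_probes = 0` with a warning.
#'
#' @param path path to SEG TSV.
#' @return data.frame `SegmentTable` with columns
#'   `sample_id`, `chrom`, `start`, `end`, `num_probes`, `seg_mean`.
#' @export
read_seg <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  cn <- tolower(colnames(df))
  pick <- function(alts) {
    i <- match(alts, cn)
    i <- i[!is.na(i)]
    if (length(i)) i[1] else NA_integer_
  }
  i_id <- pick(c("id", "sample", "sample_id"))
  i_chr <- pick(c("chrom", "chromosome", "chr"))
  i_start <- pick(c("loc.start", "start"))
  i_end <- pick(c("loc.end", "end"))
  i_mark <- pick(c("num.mark", "num_probes", "num.probes"))
  i_mean <- pick(c("seg.mean", "seg_mean"))
  if (anyNA(c(i_id, i_chr, i_start, i_end, i_mean)))
    stop("SEG file '", path, "' missing standard columns")
  if (is.na(i_mark)) {
    warning("SEG file '", path, "' has no num.mark column; num_probes set to 0")
    probes <- rep(0L, nrow(df))
  } else probes <- as.integer(df[[i_mark]])
  segment_table(data.frame(
    sample_id = as.character(df[[i_id]]),
    chrom = as.character(df[[i_chr]]),
    start = as.numeric(df[[i_start]]),
    end = as.numeric(df[[i_end]]),
    num_probes = probes,
    seg_mean = as.numeric(df[[i_mean]]),
    stringsAsFactors = FALSE))
}

#' Validate a segment table
#' @param df data.frame with sample_id, chrom, start, end, num_probes,
#'   seg_mean (1-based inclusive coordinates).
#' @return the validated data.frame, classed `SegmentTable`.
#' @export
segment_table <- function(df) {
  req <- c("sample_id", "chrom", "start", "end", "num_probes", "seg_mean")
  miss <- setdiff(req, colnames(df))
  if (length(miss)) stop("segment table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$start > df$end))
    stop("segment with start > end at row ",
         which(df$start > df$end)[1])
  if (any(df$num_probes < 0)) stop("negative num_probes")
  class(df) <- unique(c("SegmentTable", class(df)))
  df
}

#' Write a segment table in SEG format
#' @param df a `SegmentTable`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(df, path) {
  out <- data.frame(ID = df$sample_id, chrom = df$chrom,
                    loc.start = df$start, loc.end = df$end,
                    num.mark = df$num_probes, seg.mean = df$seg_mean,
                    stringsAsFactors = FALSE)
  .write_tsv(out, path)
}

#' Read gene coordinates from BED4
#'
#' BED intervals are 0-based half-open on disk; they are converted to
#' 1-based inclusive here, once, so all overlap logic downstream works on a
#' single convention.
#'
#' @param path path to a BED4 file (chrom, start, end, name; no header).
#' @return data.frame `GeneCoordinates` with columns
#'   `gene`, `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("BED4 file '", path, "' needs 4 columns")
  gene_coordinates(data.frame(
    gene = as.character(df[[4]]),
    chrom = as.character(df[[1]]),
    start = as.numeric(df[[2]]) + 1,  # 0-based -> 1-based
    end = as.numeric(df[[3]]),        # half-open end == inclusive end
    stringsAsFactors = FALSE))
}

#' Validate a gene coordinate table (1-based inclusive)
#' @param df data.frame with gene, chrom, start, end.
#' @return the validated data.frame, classed `GeneCoordinates`.
#' @export
gene_coordinates <- function(df) {
  req <- c("gene", "chrom", "start", "end")
  miss <- setdiff(req, colnames(df))
  if (length(miss)) stop("gene coordinates missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$start > df$end)) stop("gene interval with start > end")
  class(df) <- unique(c("GeneCoordinates", class(df)))
  df
}

#' Write gene coordinates as BED4
#' @param df a `GeneCoordinates` table (1-based inclusive in memory).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  out <- data.frame(df$chrom, df$start - 1, df$end, df$gene)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
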