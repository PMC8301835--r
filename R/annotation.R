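#' Construct a circular genome annotation
#'
#' A genome annotation is a tibble with one row per gene (`gene_id`, `tss`,
#' `strand`) plus the length of the circular chromosome carried as an
#' attribute. All coordinates are 0-based; the chromosome is treated as
#' circular everywhere downstream, so a TSS near the end of the sequence is a
#' near neighbour of a TSS near position 0.
#'
#' @param genes data frame with columns `gene_id` (unique character), `tss`
#'   (integer in `[0, chromosome_length)`) and `strand` (`"+"` or `"-"`).
#' @param chromosome_length chromosome length in base pairs.
#' @return A tibble of class `genome_annotation` with attribute
#'   `chromosome_length`.
#' @export
#' @examples
#' ann <- genome_annotation(
#'   data.frame(gene_id = c("a", "b"), tss = c(0, 5000), strand = c("+", "-")),
#'   chromosome_length = 10000
#' )
#' chromosome_length(ann)
genome_annotation <- function(genes, chromosome_length) {
  stopifnot(is.data.frame(genes))
  need <- c("gene_id", "tss", "strand")
  miss <- setdiff(need, names(genes))
  if (length(miss) > 0) {
    abort2("annotation is missing column(s): ", paste(miss, collapse = ", "))
  }
  chromosome_length <- as.numeric(chromosome_length)
  if (length(chromosome_length) != 1 || !is.finite(chromosome_length) ||
      chromosome_length <= 0) {
    abort2("chromosome_length must be a positive number")
  }
  genes <- as_tibble(genes)[need]
  genes$gene_id <- as.character(genes$gene_id)
  genes$tss <- as.numeric(genes$tss)
  genes$strand <- as.character(genes$strand)

  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0) {
    abort2("duplicate gene_id(s): ", paste(unique(dup), collapse = ", "))
  }
  bad <- genes$gene_id[genes$tss < 0 | genes$tss >= chromosome_length]
  if (length(bad) > 0) {
    abort2(
      "tss outside [0, chromosome_length) for gene(s): ",
      paste(bad, collapse = ", ")
    )
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    abort2("strand must be '+' or '-'")
  }
  structure(
    genes,
    chromosome_length = chromosome_length,
    class = c("genome_annotation", class(tibble()))
  )
}

#' Chromosome length of an annotation
#' @param annotation a `genome_annotation`.
#' @return Length in base pairs.
#' @export
chromosome_length <- function(annotation) {
  len <- attr(annotation, "chromosome_length")
  if (is.null(len)) abort2("object carries no chromosome_length attribute")
  len
}

#' Read a genome annotation from TSV or GFF3
#'
#' The TSV dialect has a first line `#chromosome_length=<bp>` followed by a
#' header `gene_id<TAB>tss<TAB>strand` with 0-based TSS coordinates. GFF3
#' input takes `gene` features and a `##sequence-region` directive for the
#' chromosome length; 1-based GFF coordinates are converted at the boundary
#' (TSS = `start - 1` for `+` genes, `end - 1` for `-` genes).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"tsv"` or `"gff3"`.
#' @return A `genome_annotation`.
#' @export
read_annotation <- function(path, format = c("auto", "tsv", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort2("annotation file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) {
      "gff3"
    } else {
      "tsv"
    }
  }
  if (format == "gff3") read_annotation_gff3(path) else read_annotation_tsv(path)
}

read_annotation_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("^#\\s*chromosome_length\\s*=\\s*([0-9]+)", first))[[1]]
  if (length(m) < 2) {
    abort2(
      "TSV annotation must start with '#chromosome_length=<bp>' (got: ",
      substr(first, 1, 60), ")"
    )
  }
  len <- as.numeric(m[2])
  genes <- readr::read_tsv(
    path,
    comment = "#",
    col_types = readr::cols(
      gene_id = readr::col_character(),
      tss = readr::col_double(),
      strand = readr::col_character()
    )
  )
  genome_annotation(genes, len)
}

read_annotation_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort2("reading GFF3 requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  if (length(gr) == 0) abort2("no gene features in GFF3: ", path)
  len <- GenomeInfoDb::seqlengths(gr)[1]
  if (is.na(len)) {
    # rtracklayer does not always propagate ##sequence-region; parse it
    hdr <- grep("^##sequence-region", readLines(path, n = 100), value = TRUE)
    if (length(hdr) > 0) {
      len <- as.numeric(tail(strsplit(hdr[1], "\\s+")[[1]], 1))
    }
  }
  if (is.na(len)) {
    abort2("GFF3 must declare the chromosome length via ##sequence-region")
  }
  ids <- gr$ID %||% gr$gene_id
  if (is.null(ids) || anyNA(ids)) abort2("GFF3 gene features must carry an ID attribute")
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*")) abort2("GFF3 gene features must be stranded")
  tss <- ifelse(strand == "+", BiocGenerics::start(gr) - 1L, BiocGenerics::end(gr) - 1L)
  genome_annotation(
    tibble(gene_id = as.character(ids), tss = tss, strand = strand),
    chromosome_length = as.numeric(len)
  )
}

#' Write a genome annotation
#'
#' Writes the TSV dialect read back by [read_annotation()] (or GFF3 when
#' `format = "gff3"`). Gene features in GFF3 output are single-base intervals
#' at the TSS, which round-trips the TSS exactly.
#'
#' @param annotation a `genome_annotation`.
#' @param path output path.
#' @param format `"tsv"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  len <- chromosome_length(annotation)
  if (format == "tsv") {
    writeLines(sprintf("#chromosome_length=%d", as.integer(len)), path)
    readr::write_tsv(as_tibble(annotation), path, append = TRUE, col_names = TRUE)
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE) ||
        !requireNamespace("GenomicRanges", quietly = TRUE)) {
      abort2("writing GFF3 requires rtracklayer and GenomicRanges")
    }
    gr <- GenomicRanges::GRanges(
      seqnames = "chr",
      ranges = IRanges::IRanges(start = annotation$tss + 1L, width = 1L),
      strand = annotation$strand,
      type = "gene",
      ID = annotation$gene_id
    )
    GenomeInfoDb::seqlengths(gr) <- as.integer(len)
    rtracklayer::export(gr, path, format = "gff3")
    # rtracklayer omits the ##sequence-region directive; loaders need it
    lines <- readLines(path)
    if (!any(grepl("^##sequence-region", lines))) {
      writeLines(
        append(lines, sprintf("##sequence-region chr 1 %d", as.integer(len)), after = 1),
        path
      )
    }
  }
  invisible(path)
}
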