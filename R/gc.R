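#' Read a genome sequence from FASTA
#'
#' Expects a single circular contig over the alphabet A/C/G/T/N; any other
#' ambiguity code is rejected at load so downstream GC arithmetic stays
#' simple (N is handled per position).
#'
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet] of length 1.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) abort2("FASTA not found: ", path)
  g <- Biostrings::readDNAStringSet(path)
  if (length(g) != 1) {
    abort2("expected a single circular contig, got ", length(g))
  }
  freq <- Biostrings::alphabetFrequency(g[[1]])
  other <- sum(freq) - sum(freq[c("A", "C", "G", "T", "N")])
  if (other > 0) {
    abort2("genome contains ambiguity characters other than N")
  }
  g
}

#' Extract promoter sequence contexts around each TSS
#'
#' For every gene, takes the window `[-upstream, +downstream)` relative to
#' the transcription start site (position 0 = TSS) read 5'->3' on the coding
#' strand: minus-strand genes are reverse-complemented so that position +1 is
#' always downstream of transcription start. Extraction is circular, so
#' contexts may wrap through the coordinate origin. Contexts that are more
#' than half N are flagged.
#'
#' @param genome a `DNAStringSet` of length 1 (or `DNAString`) matching the
#'   annotation's chromosome length.
#' @param annotation a `genome_annotation`.
#' @param upstream,downstream bp upstream/downstream of the TSS
#'   (defaults 300 and 200).
#' @param gene_set optional subset of gene ids (default: all genes).
#' @return A tibble of class `promoter_contexts` with columns `gene_id`,
#'   `strand`, `sequence` (character), `n_fraction`, `flagged`; attributes
#'   `upstream`, `downstream`.
#' @export
extract_contexts <- function(genome, annotation, upstream = 300,
                             downstream = 200, gene_set = NULL) {
  if (inherits(genome, "DNAStringSet")) {
    if (length(genome) != 1) abort2("genome must contain a single contig")
    genome <- genome[[1]]
  }
  if (!inherits(genome, "DNAString")) abort2("genome must be a DNAString(Set)")
  len <- chromosome_length(annotation)
  if (length(genome) != len) {
    abort2("FASTA length (", length(genome),
           ") does not match annotation chromosome length (", len, ")")
  }
  width <- upstream + downstream
  if (width <= 0 || width > len) abort2("invalid context span")

  ann <- as_tibble(annotation)
  if (!is.null(gene_set)) {
    unknown <- setdiff(gene_set, ann$gene_id)
    if (length(unknown) > 0) {
      abort2("gene(s) absent from annotation: ", paste(head(unknown, 5), collapse = ", "))
    }
    ann <- ann[ann$gene_id %in% gene_set, , drop = FALSE]
  }
  if (nrow(ann) == 0) abort2("no genes to extract contexts for")

  # genomic start (0-based) of the context on the forward strand:
  # plus strand covers [tss - upstream, tss + downstream),
  # minus strand covers [tss - downstream + 1, tss + upstream + 1)
  g0 <- ifelse(ann$strand == "+", ann$tss - upstream, ann$tss - downstream + 1)
  g0 <- g0 %% len
  doubled <- Biostrings::xscat(genome, genome) # circular extraction
  ctx <- Biostrings::extractAt(doubled, IRanges::IRanges(start = g0 + 1, width = width))
  minus <- ann$strand == "-"
  if (any(minus)) {
    ctx[minus] <- Biostrings::reverseComplement(ctx[minus])
  }
  n_frac <- Biostrings::letterFrequency(ctx, "N", as.prob = TRUE)[, 1]
  flagged <- n_frac > 0.5
  if (any(flagged)) {
    message(sum(flagged), " context(s) flagged: more than 50% N")
  }
  structure(
    tibble(
      gene_id = ann$gene_id,
      strand = ann$strand,
      sequence = as.character(ctx),
      n_fraction = unname(n_frac),
      flagged = flagged
    ),
    upstream = upstream,
    downstream = downstream,
    class = c("promoter_contexts", class(tibble()))
  )
}

#' TSS-anchored GC-content profile of a gene set
#'
#' At each position relative to the TSS, the fraction of G or C bases across
#' the contexts (N excluded from numerator and denominator), followed by a
#' centred moving average of odd width `smoothing`. Position 0 is the TSS;
#' negative positions are upstream on the coding strand.
#'
#' @param contexts a `promoter_contexts` tibble (same span for all contexts).
#' @param smoothing moving-average width in bp; odd, `<=` span (default 21).
#'   Use 1 for no smoothing.
#' @return A tibble of class `gc_profile` with columns `position`, `gc`
#'   (smoothed), `gc_raw`, `n_used`; attributes `smoothing`, `n_sequences`,
#'   `upstream`, `downstream`.
#' @export
gc_profile <- function(contexts, smoothing = 21) {
  if (!inherits(contexts, "promoter_contexts")) {
    abort2("contexts must come from extract_contexts()")
  }
  if (nrow(contexts) == 0) abort2("no contexts supplied")
  up <- attr(contexts, "upstream")
  down <- attr(contexts, "downstream")
  span <- up + down
  if (smoothing %% 2 == 0 || smoothing > span) {
    abort2("smoothing must be odd and no wider than the span")
  }
  seqs <- Biostrings::DNAStringSet(contexts$sequence)
  if (length(unique(Biostrings::width(seqs))) != 1) {
    abort2("contexts differ in span")
  }
  cm <- Biostrings::consensusMatrix(seqs)[c("A", "C", "G", "T", "N"), , drop = FALSE]
  usable <- colSums(cm[c("A", "C", "G", "T"), , drop = FALSE])
  gc_raw <- ifelse(usable > 0, (cm["C", ] + cm["G", ]) / usable, NA_real_)
  if (anyNA(gc_raw)) {
    warn2(sum(is.na(gc_raw)), " position(s) have no usable (non-N) sequence")
  }
  gc <- if (anyNA(gc_raw)) {
    smooth_na(gc_raw, smoothing)
  } else {
    moving_average(gc_raw, smoothing)
  }
  structure(
    tibble(
      position = seq(-up, down - 1),
      gc = gc,
      gc_raw = gc_raw,
      n_used = as.integer(usable)
    ),
    smoothing = smoothing,
    n_sequences = nrow(contexts),
    upstream = up,
    downstream = down,
    class = c("gc_profile", class(tibble()))
  )
}

# moving average tolerating NA positions (kept NA in the output, ignored in
# neighbouring windows)
smooth_na <- function(x, k) {
  h <- (k - 1L) / 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    if (is.na(x[i])) return(NA_real_)
    w <- x[max(1L, i - h):min(n, i + h)]
    mean(w, na.rm = TRUE)
  }, numeric(1))
}

#' @export
glance.gc_profile <- function(x, ...) {
  tibble(
    n_sequences = attr(x, "n_sequences"),
    smoothing = attr(x, "smoothing"),
    mean_gc = mean(x$gc, na.rm = TRUE),
    span = nrow(x)
  )
}

#' Compare the GC profiles of two gene sets against the genome background
#'
#' Aligns the profiles of two gene sets and of all genes on their common
#' span and reports the per-position difference `set_a - set_b` plus its mean
#' over the span — the two-sets-against-background comparison used to ask
#' whether one expression class sits in more GC-rich promoter contexts than
#' another.
#'
#' @param profile_a,profile_b,profile_all `gc_profile`s with identical spans
#'   and smoothing.
#' @return A tibble of class `gc_comparison` with columns `position`,
#'   `gc_all`, `gc_a`, `gc_b`, `diff`; attribute `mean_diff`.
#' @export
compare_gc_profiles <- function(profile_a, profile_b, profile_all) {
  ps <- list(profile_a, profile_b, profile_all)
  if (!all(vapply(ps, inherits, logical(1), "gc_profile"))) {
    abort2("all three inputs must be gc_profiles")
  }
  if (!identical(profile_a$position, profile_b$position) ||
      !identical(profile_a$position, profile_all$position)) {
    abort2("profiles have mismatched spans")
  }
  sm <- vapply(ps, attr, numeric(1), "smoothing")
  if (length(unique(sm)) != 1) abort2("profiles have mismatched smoothing")
  out <- tibble(
    position = profile_a$position,
    gc_all = profile_all$gc,
    gc_a = profile_a$gc,
    gc_b = profile_b$gc,
    diff = profile_a$gc - profile_b$gc
  )
  structure(
    out,
    mean_diff = mean(out$diff, na.rm = TRUE),
    class = c("gc_comparison", class(tibble()))
  )
}

#' @export
glance.gc_comparison <- function(x, ...) {
  tibble(mean_diff = attr(x, "mean_diff"), span = nrow(x))
}

#' Write a GC comparison table to TSV
#'
#' Columns `position gc_all gc_setA gc_setB n_used` (n_used from the
#' background profile when supplied).
#'
#' @param cmp a `gc_comparison`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gc_comparison <- function(cmp, path) {
  readr::write_tsv(as_tibble(cmp), path)
  invisible(path)
}
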