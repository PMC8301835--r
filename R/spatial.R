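#' Sliding-window grid on a circular chromosome
#'
#' Windows are half-open intervals `[start, start + window_size)` taken modulo
#' the chromosome length, so the last windows wrap across the origin. With the
#' defaults (100 kb windows every 10 kb) the grid is a smooth sliding scan;
#' set `step = window_size` for disjoint tiles.
#'
#' @param chromosome_length chromosome length in bp.
#' @param window_size window width in bp (default 100 kb).
#' @param step distance between window starts in bp (default 10 kb).
#' @param offset start of the first window (bp); rotating the grid together
#'   with the gene coordinates leaves every downstream profile unchanged.
#' @return A tibble of class `window_grid` with columns `window`, `start`,
#'   `end` (`start + window_size`, possibly past the chromosome end to mark a
#'   wrap) and `wraps`; attributes record the grid parameters.
#' @export
make_grid <- function(chromosome_length, window_size = 1e5, step = 1e4,
                      offset = 0) {
  if (window_size > chromosome_length) {
    abort2("window_size exceeds chromosome length")
  }
  if (step <= 0 || step > window_size) {
    abort2("step must satisfy 0 < step <= window_size")
  }
  n <- ceiling(chromosome_length / step)
  start <- (offset + (seq_len(n) - 1) * step) %% chromosome_length
  end <- start + window_size
  out <- tibble(
    window = seq_len(n),
    start = start,
    end = end,
    wraps = end > chromosome_length
  )
  structure(
    out,
    chromosome_length = chromosome_length,
    window_size = window_size,
    step = step,
    offset = offset,
    class = c("window_grid", class(tibble()))
  )
}

# TRUE when tss falls in [start, start + window) on the circle
in_window <- function(tss, start, window_size, len) {
  ((tss - start) %% len) < window_size
}

# Sparse genes x windows membership indicator (each gene hits roughly
# window_size / step windows); shared by observed counts and the
# Monte-Carlo null.
window_membership <- function(annotation, grid) {
  len <- chromosome_length(annotation)
  w <- attr(grid, "window_size")
  hits <- lapply(seq_len(nrow(grid)), function(j) {
    which(in_window(annotation$tss, grid$start[j], w, len))
  })
  j <- rep.int(seq_len(nrow(grid)), lengths(hits))
  Matrix::sparseMatrix(
    i = unlist(hits), j = j, x = 1,
    dims = c(nrow(annotation), nrow(grid))
  )
}

#' Per-window counts of a gene set
#'
#' A gene contributes to every window containing its TSS (genes are treated
#' as points, so long genes carry no extra weight).
#'
#' @param annotation a `genome_annotation`.
#' @param gene_set character vector of gene ids (must be a subset of the
#'   annotation).
#' @param grid a `window_grid` built for the same chromosome length.
#' @return The grid tibble with an added integer column `observed`.
#' @export
window_counts <- function(annotation, gene_set, grid) {
  check_grid(annotation, grid)
  gene_set <- unique(gene_set)
  unknown <- setdiff(gene_set, annotation$gene_id)
  if (length(unknown) > 0) {
    abort2("gene(s) absent from annotation: ", paste(head(unknown, 5), collapse = ", "))
  }
  if (length(gene_set) == 0) warn2("empty gene set: all window counts are zero")
  tss <- annotation$tss[annotation$gene_id %in% gene_set]
  len <- chromosome_length(annotation)
  w <- attr(grid, "window_size")
  obs <- vapply(
    grid$start,
    function(s) sum(in_window(tss, s, w, len)),
    integer(1)
  )
  out <- grid
  out$observed <- obs
  out
}

check_grid <- function(annotation, grid) {
  if (!inherits(grid, "window_grid")) abort2("grid must come from make_grid()")
  if (!isTRUE(all.equal(chromosome_length(annotation), attr(grid, "chromosome_length")))) {
    abort2("grid and annotation disagree on chromosome length")
  }
  invisible(TRUE)
}

#' Null moments of window counts for random gene sets
#'
#' The null model draws `n` genes uniformly without replacement from all
#' annotated genes and counts them per window. `method = "montecarlo"`
#' estimates the per-window mean and SD from `n_samples` draws (the
#' resampling scheme behind the default 10,000-sample Z-scores);
#' `method = "analytic"` returns the exact hypergeometric moments
#' \eqn{\mu_w = n k_w / N} and
#' \eqn{\sigma^2_w = n (k_w/N)(1 - k_w/N)(N-n)/(N-1)}, where \eqn{k_w} is the
#' number of annotated genes in window \eqn{w} and \eqn{N} the total gene
#' count. The two agree as `n_samples` grows.
#'
#' @inheritParams window_counts
#' @param n size of the gene sets drawn under the null; `n = N` gives SD 0
#'   in every window (flagged).
#' @param n_samples number of Monte-Carlo draws (default 10,000).
#' @param seed RNG seed for the Monte-Carlo draws.
#' @param method `"montecarlo"` or `"analytic"`.
#' @return The grid tibble with added columns `null_mean` and `null_sd`;
#'   attributes `set_size`, `n_samples`, `seed`, `method`.
#' @export
null_moments <- function(annotation, n, grid, n_samples = 10000, seed = NULL,
                         method = c("montecarlo", "analytic")) {
  method <- match.arg(method)
  check_grid(annotation, grid)
  N <- nrow(annotation)
  if (n <= 0 || n > N) abort2("set size n must satisfy 0 < n <= ", N)
  out <- grid

  if (method == "analytic") {
    k <- window_counts(annotation, annotation$gene_id, grid)$observed
    out$null_mean <- n * k / N
    out$null_sd <- sqrt(n * (k / N) * (1 - k / N) * (N - n) / (N - 1))
    n_samples <- NA_integer_
  } else {
    if (n_samples < 100) warn2("n_samples < 100: Monte-Carlo null will be noisy")
    M <- window_membership(annotation, grid)
    draws <- with_seed_if(seed, {
      vapply(seq_len(n_samples), function(i) sample.int(N, n), integer(n))
    })
    draws <- matrix(draws, nrow = n) # robust to n = 1
    S <- Matrix::sparseMatrix(
      i = rep(seq_len(n_samples), each = n),
      j = as.vector(draws),
      x = 1,
      dims = c(n_samples, N)
    )
    counts <- as.matrix(S %*% M) # n_samples x n_windows
    out$null_mean <- colMeans(counts)
    out$null_sd <- apply(counts, 2, sd)
  }
  if (n == N) message("n equals the total gene count: null SD is 0 in every window")

  structure(
    out,
    set_size = n,
    n_samples = n_samples,
    seed = seed,
    method = method,
    class = class(grid)
  )
}

#' Z-scores and enrichment calls from observed counts and null moments
#'
#' Standardises each window's observed count against the resampling null,
#' `z = (observed - null_mean) / null_sd`, and calls windows `enriched`
#' (`z > threshold`), `depleted` (`z < -threshold`) or `ns`. Windows with a
#' degenerate null (`null_sd = 0`) are called `undefined` rather than
#' producing infinite scores.
#'
#' @param counts output of [window_counts()] (grid + `observed`).
#' @param moments output of [null_moments()] on the same grid.
#' @param threshold |Z| call threshold (default 2, i.e. enrichment at Z > 2
#'   and depletion at Z < -2).
#' @param set_name optional label stored in the profile metadata.
#' @return A tibble of class `zprofile` with columns `window`, `start`,
#'   `end`, `wraps`, `observed`, `null_mean`, `null_sd`, `z`, `call`.
#' @export
z_from_counts <- function(counts, moments, threshold = 2, set_name = NULL) {
  if (!identical(counts$start, moments$start) ||
      !identical(counts$end, moments$end)) {
    abort2("counts and moments must share one window grid")
  }
  z <- ifelse(
    moments$null_sd > 0,
    (counts$observed - moments$null_mean) / moments$null_sd,
    ifelse(counts$observed == moments$null_mean, 0, NA_real_)
  )
  call <- dplyr::case_when(
    moments$null_sd == 0 ~ "undefined",
    z > threshold ~ "enriched",
    z < -threshold ~ "depleted",
    TRUE ~ "ns"
  )
  out <- counts
  out$null_mean <- moments$null_mean
  out$null_sd <- moments$null_sd
  out$z <- z
  out$call <- call
  structure(
    out,
    set_name = set_name,
    set_size = attr(moments, "set_size"),
    total_genes = NULL,
    threshold = threshold,
    n_samples = attr(moments, "n_samples"),
    seed = attr(moments, "seed"),
    method = attr(moments, "method"),
    class = c("zprofile", class(tibble()))
  )
}

#' Spatial enrichment Z-profile of a gene set
#'
#' Convenience wrapper: counts the set per window, estimates the null for a
#' random set of the same size, and standardises. This is the per-window
#' enrichment scan used to compare the genomic organisation of regulons and
#' couplons.
#'
#' @inheritParams window_counts
#' @inheritParams null_moments
#' @inheritParams z_from_counts
#' @return A `zprofile` tibble (see [z_from_counts()]).
#' @export
#' @examples
#' ann <- genome_annotation(
#'   data.frame(gene_id = paste0("g", 1:40), tss = (0:39) * 250, strand = "+"),
#'   10000
#' )
#' zp <- z_profile(ann, paste0("g", 1:6), make_grid(10000, 2000, 2000),
#'                 method = "analytic")
#' zp$call
z_profile <- function(annotation, gene_set, grid, threshold = 2,
                      n_samples = 10000, seed = NULL,
                      method = c("montecarlo", "analytic"),
                      set_name = NULL) {
  method <- match.arg(method)
  counts <- window_counts(annotation, gene_set, grid)
  mom <- null_moments(
    annotation, length(unique(gene_set)), grid,
    n_samples = n_samples, seed = seed, method = method
  )
  out <- z_from_counts(counts, mom, threshold = threshold, set_name = set_name)
  attr(out, "total_genes") <- nrow(annotation)
  out
}

#' Pearson correlation between two spatial Z-profiles
#'
#' Correlates the per-window Z-scores of two profiles on the same grid —
#' the statistic used to compare the genomic organisation of couplons with
#' their parent regulons. Windows with an undefined Z in either profile are
#' excluded pairwise.
#'
#' @param a,b `zprofile` tibbles on the same grid.
#' @return A one-row tibble with `r`, `n_windows` (windows used) and `flag`
#'   (`"ok"`, or `"zero_variance"` when either profile is flat, in which case
#'   `r` is `NA`).
#' @export
spatial_correlation <- function(a, b) {
  if (!identical(a$start, b$start) || !identical(a$end, b$end)) {
    abort2("profiles must share one window grid")
  }
  use <- a$call != "undefined" & b$call != "undefined" & !is.na(a$z) & !is.na(b$z)
  if (sum(use) < 3) abort2("fewer than 3 usable windows shared by the profiles")
  za <- a$z[use]
  zb <- b$z[use]
  if (sd(za) == 0 || sd(zb) == 0) {
    warn2("zero variance in a Z-profile: correlation undefined")
    return(tibble(r = NA_real_, n_windows = sum(use), flag = "zero_variance"))
  }
  tibble(r = cor(za, zb), n_windows = sum(use), flag = "ok")
}

#' @export
tidy.zprofile <- function(x, ...) as_tibble(x)

#' @export
glance.zprofile <- function(x, ...) {
  tibble(
    set_name = attr(x, "set_name") %||% NA_character_,
    set_size = attr(x, "set_size") %||% NA_integer_,
    n_windows = nrow(x),
    n_enriched = sum(x$call == "enriched"),
    n_depleted = sum(x$call == "depleted"),
    max_z = max(x$z, na.rm = TRUE),
    method = attr(x, "method") %||% NA_character_,
    n_samples = attr(x, "n_samples") %||% NA_integer_
  )
}

#' Write a Z-profile as TSV and BED-like records
#'
#' The TSV carries one joint record per window
#' (`start end observed null_mean null_sd z call`). Windows wrapping the
#' origin additionally appear as two split BED lines when `bed_path` is
#' given, since BED intervals cannot cross the coordinate origin.
#'
#' @param zp a `zprofile`.
#' @param path TSV output path.
#' @param bed_path optional BED output path.
#' @return `path`, invisibly.
#' @export
write_zprofile <- function(zp, path, bed_path = NULL) {
  readr::write_tsv(
    as_tibble(zp)[c("start", "end", "observed", "null_mean", "null_sd", "z", "call")],
    path
  )
  if (!is.null(bed_path)) {
    len <- attr(zp, "chromosome_length")
    name <- sprintf("w%d_z=%.3f_%s", zp$window, zp$z, zp$call)
    plain <- tibble(
      chrom = "chr",
      start = zp$start,
      end = pmin(zp$end, len),
      name = name,
      score = zp$z
    )
    wrapped <- tibble(
      chrom = "chr",
      start = 0,
      end = zp$end[zp$wraps] - len,
      name = name[zp$wraps],
      score = zp$z[zp$wraps]
    )
    readr::write_tsv(bind_rows(plain, wrapped), bed_path, col_names = FALSE)
  }
  invisible(path)
}
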