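#' Construct an expression time-course
#'
#' A genes x timepoints table of non-negative expression values sampled along
#' the growth cycle (the reference design samples at 60, 120, 180, 300 and
#' 420 minutes after inoculation). Rows with missing values are dropped and
#' counted; timepoint columns are ordered strictly increasing.
#'
#' @param values data frame with a `gene_id` column plus one numeric column
#'   per timepoint, named by the time in minutes.
#' @return A tibble of class `expression_timecourse` with attributes
#'   `timepoints` (numeric, minutes) and `n_dropped`.
#' @export
as_timecourse <- function(values) {
  stopifnot(is.data.frame(values))
  if (!"gene_id" %in% names(values)) abort2("time-course needs a gene_id column")
  tp_cols <- setdiff(names(values), "gene_id")
  tp <- suppressWarnings(as.numeric(tp_cols))
  if (anyNA(tp)) {
    abort2("timepoint columns must be named by time in minutes; got: ",
           paste(tp_cols[is.na(tp)], collapse = ", "))
  }
  if (length(tp) < 2) abort2("at least 2 timepoints are required")
  ord <- order(tp)
  tp <- tp[ord]
  if (any(diff(tp) <= 0)) abort2("timepoints must be strictly increasing (duplicates?)")
  out <- as_tibble(values)[c("gene_id", tp_cols[ord])]
  out$gene_id <- as.character(out$gene_id)
  if (anyDuplicated(out$gene_id)) abort2("duplicate gene_id in time-course")

  complete <- stats::complete.cases(out)
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    message(n_dropped, " gene(s) dropped from time-course: missing values")
    out <- out[complete, , drop = FALSE]
  }
  structure(
    out,
    timepoints = tp,
    n_dropped = n_dropped,
    class = c("expression_timecourse", class(tibble()))
  )
}

#' Timepoints of a time-course or profile, in minutes
#' @param x an `expression_timecourse` or `temporal_profile`.
#' @return Numeric vector of minutes after inoculation.
#' @export
timepoints <- function(x) {
  tp <- attr(x, "timepoints")
  if (is.null(tp)) abort2("object carries no timepoints attribute")
  tp
}

#' Read / write an expression time-course TSV
#'
#' Header is `gene_id` plus one column per timepoint (minutes).
#'
#' @param path TSV path.
#' @return [read_timecourse()]: an `expression_timecourse`;
#'   [write_timecourse()]: `path`, invisibly.
#' @export
read_timecourse <- function(path) {
  if (!file.exists(path)) abort2("expression file not found: ", path)
  as_timecourse(readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()
  )))
}

#' @rdname read_timecourse
#' @param tc an `expression_timecourse`.
#' @export
write_timecourse <- function(tc, path) {
  readr::write_tsv(as_tibble(tc), path)
  invisible(path)
}

# expression matrix (genes x timepoints) with gene_id rownames
tc_matrix <- function(tc) {
  m <- as.matrix(as_tibble(tc)[, -1])
  rownames(m) <- tc$gene_id
  m
}

#' Min-max normalisation of one expression pattern to [0, 1]
#'
#' `x' = (x - min) / (max - min)`. The transform is invariant to positive
#' affine rescaling of the input, which is what makes genes with different
#' absolute expression comparable before averaging. A constant pattern has no
#' shape to keep: it returns all-`NA` with a warning, and set-level averages
#' exclude such genes.
#'
#' @param x numeric vector of per-timepoint values (length >= 2).
#' @return Numeric vector in `[0, 1]`, or all-`NA` for constant input.
#' @export
#' @examples
#' normalize_unit(c(2, 4, 6, 4, 2))
normalize_unit <- function(x) {
  if (length(x) < 2) abort2("normalize_unit needs at least 2 values")
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warn2("constant pattern: normalisation undefined")
    return(rep(NA_real_, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Average temporal profile of a gene set
#'
#' The profile of a regulon or couplon is computed in the fixed order: each
#' member gene's pattern is min-max normalised to `[0, 1]` individually
#' (constant genes excluded and counted), the normalised patterns are averaged
#' per timepoint with equal gene weights, and the averaged curve is finally
#' rescaled to `[0, 1]`. The extremes of the averaged curve *before* that
#' final rescale are retained as `pre_norm_min` / `pre_norm_max` — they say
#' how synchronous the set is (a tight set averages close to 0 and 1, a
#' heterogeneous set averages towards 0.5).
#'
#' @param tc an `expression_timecourse`.
#' @param gene_set character vector of member gene ids.
#' @param set_name optional label.
#' @return A tibble of class `temporal_profile` with columns `time`, `value`,
#'   and attributes `set_name`, `pre_norm_min`, `pre_norm_max`,
#'   `n_genes_used`, `n_excluded` (constant or absent members) and
#'   `degenerate` (TRUE when the averaged curve was constant; values are then
#'   all 0.5).
#' @export
set_profile <- function(tc, gene_set, set_name = NULL) {
  m <- tc_matrix(tc)
  gene_set <- unique(gene_set)
  present <- intersect(gene_set, rownames(m))
  sub <- m[present, , drop = FALSE]
  keep <- apply(sub, 1, function(r) max(r) > min(r))
  n_excluded <- length(gene_set) - sum(keep)
  if (sum(keep) == 0) {
    abort2("no usable genes in set", if (!is.null(set_name)) paste0(" '", set_name, "'"),
           ": all members absent or constant")
  }
  sub <- sub[keep, , drop = FALSE]
  norm <- t(apply(sub, 1, function(r) {
    rng <- range(r)
    (r - rng[1]) / (rng[2] - rng[1])
  }))
  avg <- unname(colMeans(norm))
  pre_min <- min(avg)
  pre_max <- max(avg)
  degenerate <- pre_max == pre_min
  value <- if (degenerate) {
    warn2("averaged curve is constant: degenerate profile (all 0.5)")
    rep(0.5, length(avg))
  } else {
    (avg - pre_min) / (pre_max - pre_min)
  }
  structure(
    tibble(time = timepoints(tc), value = value),
    set_name = set_name,
    pre_norm_min = pre_min,
    pre_norm_max = pre_max,
    n_genes_used = sum(keep),
    n_excluded = n_excluded,
    degenerate = degenerate,
    timepoints = timepoints(tc),
    class = c("temporal_profile", class(tibble()))
  )
}

#' @export
glance.temporal_profile <- function(x, ...) {
  tibble(
    set_name = attr(x, "set_name") %||% NA_character_,
    n_genes_used = attr(x, "n_genes_used"),
    n_excluded = attr(x, "n_excluded"),
    pre_norm_min = attr(x, "pre_norm_min"),
    pre_norm_max = attr(x, "pre_norm_max"),
    degenerate = attr(x, "degenerate")
  )
}

#' Pearson correlation between two temporal profiles
#'
#' With the reference five-timepoint design this is a correlation over n = 5
#' points; the number of points is attached as attribute `n` and no p-value
#' is reported.
#'
#' @param p,q `temporal_profile`s on identical timepoints.
#' @return Pearson r (numeric scalar, attribute `n`), `NA` with a warning if
#'   either profile is constant.
#' @export
profile_correlation <- function(p, q) {
  if (!isTRUE(all.equal(p$time, q$time))) {
    abort2("profiles must share identical timepoints")
  }
  if (sd(p$value) == 0 || sd(q$value) == 0) {
    warn2("constant profile: correlation undefined")
    return(structure(NA_real_, n = nrow(p)))
  }
  structure(cor(p$value, q$value), n = nrow(p))
}

#' Correlation between a regulator gene's expression and its regulon profile
#'
#' Correlates the min-max normalised pattern of the gene encoding a regulator
#' with the average profile of its regulon — the per-regulator statistic
#' asking whether regulon expression tracks its cognate regulatory gene.
#'
#' @param tc an `expression_timecourse`.
#' @param regulator_gene_id gene id of the regulator's own gene.
#' @param gene_set the regulon's member genes.
#' @return Pearson r (numeric scalar, attribute `n`).
#' @export
regulator_vs_regulon <- function(tc, regulator_gene_id, gene_set) {
  m <- tc_matrix(tc)
  if (!regulator_gene_id %in% rownames(m)) {
    abort2("regulator gene absent from time-course: ", regulator_gene_id)
  }
  pattern <- m[regulator_gene_id, ]
  if (max(pattern) == min(pattern)) {
    abort2("regulator gene has a constant pattern: ", regulator_gene_id)
  }
  prof <- set_profile(tc, gene_set)
  reg <- normalize_unit(pattern)
  if (sd(prof$value) == 0) {
    warn2("constant regulon profile: correlation undefined")
    return(structure(NA_real_, n = nrow(prof)))
  }
  structure(cor(reg, prof$value), n = nrow(prof))
}

#' Remapping uncertainty envelope of a set profile
#'
#' Quantifies how much a regulon/couplon profile depends on the exact gene
#' membership: in each replicate a fraction of the member genes is remapped
#' and the set profile recomputed; the envelope is the per-timepoint standard
#' deviation across replicates. `mode = "replace"` (default) swaps
#' `round(fraction * |set|)` members for genes drawn uniformly from outside
#' the set; `mode = "permute"` instead permutes the expression patterns of a
#' fraction of all genes in the genome and keeps the membership fixed.
#'
#' @inheritParams set_profile
#' @param fraction fraction of genes remapped per replicate (default 0.10).
#' @param n_reps number of replicates (default 100).
#' @param seed RNG seed.
#' @param mode `"replace"` or `"permute"`.
#' @return The set's `temporal_profile` with an added column `envelope_sd`
#'   and attributes `replicates` (n_reps x timepoints matrix of replicate
#'   profile values), `fraction`, `n_reps`, `mode`, `seed`.
#' @export
remap_envelope <- function(tc, gene_set, fraction = 0.10, n_reps = 100,
                           seed = NULL, mode = c("replace", "permute"),
                           set_name = NULL) {
  mode <- match.arg(mode)
  if (fraction < 0 || fraction > 1) abort2("fraction must be in [0, 1]")
  base <- set_profile(tc, gene_set, set_name = set_name)
  gene_set <- unique(gene_set)
  all_genes <- tc$gene_id

  n_swap <- if (mode == "replace") {
    round(fraction * length(gene_set))
  } else {
    round(fraction * length(all_genes))
  }
  if (n_swap == 0) {
    warn2("fraction rounds to 0 remapped genes: envelope is identically zero")
  }

  reps <- with_seed_if(seed, {
    vapply(seq_len(n_reps), function(i) {
      if (n_swap == 0) return(base$value)
      if (mode == "replace") {
        drop <- sample(gene_set, n_swap)
        pool <- setdiff(all_genes, gene_set)
        add <- sample(pool, min(n_swap, length(pool)))
        set_profile_quiet(tc, c(setdiff(gene_set, drop), add))
      } else {
        idx <- sample.int(length(all_genes), n_swap)
        m <- as_tibble(tc)
        m[idx, -1] <- m[idx[sample.int(length(idx))], -1]
        set_profile_quiet(as_timecourse_keep(m, timepoints(tc)), gene_set)
      }
    }, numeric(nrow(base)))
  })
  reps <- t(matrix(reps, nrow = nrow(base))) # n_reps x timepoints

  env <- apply(reps, 2, sd)
  out <- base
  out$envelope_sd <- env
  structure(
    out,
    replicates = reps,
    fraction = fraction,
    n_reps = n_reps,
    mode = mode,
    seed = seed,
    class = class(base)
  )
}

# set_profile without degenerate-profile warnings (replicates may be flat)
set_profile_quiet <- function(tc, gene_set) {
  suppressWarnings(set_profile(tc, gene_set)$value)
}

# rebuild a timecourse without re-validation (internal, columns unchanged)
as_timecourse_keep <- function(df, tp) {
  structure(
    as_tibble(df),
    timepoints = tp,
    n_dropped = 0L,
    class = c("expression_timecourse", class(tibble()))
  )
}

#' Compare set profiles between two conditions
#'
#' Side-by-side machinery for wild-type versus mutant comparisons: computes
#' each set's profile under both conditions and the Pearson correlation
#' between them. Sets whose profile is degenerate or unusable in either
#' condition get `NA` with a note in `flag`.
#'
#' @param tc_a,tc_b `expression_timecourse`s for the two conditions, on the
#'   same timepoints.
#' @param sets named list of gene-id vectors.
#' @return A tibble with one row per set: `set_name`, `r`, `n_genes_a`,
#'   `n_genes_b`, `flag`; attribute `profiles` holds the paired
#'   `temporal_profile`s.
#' @export
compare_conditions <- function(tc_a, tc_b, sets) {
  if (!isTRUE(all.equal(timepoints(tc_a), timepoints(tc_b)))) {
    abort2("conditions must share identical timepoints")
  }
  if (length(sets) == 0) {
    return(structure(
      tibble(set_name = character(), r = numeric(),
             n_genes_a = integer(), n_genes_b = integer(), flag = character()),
      profiles = list()
    ))
  }
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  profiles <- purrr::imap(sets, function(gs, nm) {
    pa <- tryCatch(set_profile(tc_a, gs, set_name = nm), error = function(e) NULL)
    pb <- tryCatch(set_profile(tc_b, gs, set_name = nm), error = function(e) NULL)
    list(a = pa, b = pb)
  })
  rows <- purrr::imap(profiles, function(pr, nm) {
    if (is.null(pr$a) || is.null(pr$b)) {
      return(tibble(set_name = nm, r = NA_real_, n_genes_a = NA_integer_,
                    n_genes_b = NA_integer_, flag = "unusable_set"))
    }
    r <- suppressWarnings(profile_correlation(pr$a, pr$b))
    tibble(
      set_name = nm,
      r = as.numeric(r),
      n_genes_a = attr(pr$a, "n_genes_used"),
      n_genes_b = attr(pr$b, "n_genes_used"),
      flag = if (is.na(r)) "degenerate_profile" else "ok"
    )
  })
  structure(bind_rows(rows), profiles = profiles)
}

#' Write a temporal profile as TSV plus a JSON sidecar
#'
#' The TSV has columns `time`, `value` and (when present) `envelope_sd`; the
#' sidecar records the pre-normalisation extremes, gene counts, flags and
#' remapping parameters.
#'
#' @param profile a `temporal_profile`.
#' @param path TSV output path; the sidecar goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  readr::write_tsv(as_tibble(profile), path)
  meta <- list(
    set_name = attr(profile, "set_name"),
    pre_norm_min = attr(profile, "pre_norm_min"),
    pre_norm_max = attr(profile, "pre_norm_max"),
    n_genes_used = attr(profile, "n_genes_used"),
    n_excluded = attr(profile, "n_excluded"),
    degenerate = attr(profile, "degenerate"),
    fraction = attr(profile, "fraction"),
    n_reps = attr(profile, "n_reps"),
    mode = attr(profile, "mode"),
    seed = attr(profile, "seed")
  )
  jsonlite::write_json(
    meta[!vapply(meta, is.null, logical(1))],
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
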