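#' Build a couplon from a NAP/global-TF regulon and a sigma-factor regulon
#'
#' A couplon is the set of genes regulated conjointly by a particular pair of
#' RNA polymerase holoenzyme (sigma factor) and NAP or global transcription
#' factor: the intersection of the two regulons' target-gene sets. Membership
#' ignores activation/repression sign; signs stay available in the regulon
#' set for optional filtering.
#'
#' @param rs a `regulon_set`.
#' @param nap name of a regulator of class `"NAP"` or `"globalTF"`.
#' @param sigma name of a regulator of class `"sigma"`.
#' @param check_classes set to `FALSE` to intersect an arbitrary regulator
#'   pair (exploratory use); the default enforces the NAP/TF-by-sigma pairing.
#' @return An object of class `couplon`: a list with `nap_or_tf`, `sigma`,
#'   `members` (sorted character vector) and `parent_sizes` (named integer
#'   vector).
#' @export
#' @examples
#' ann <- genome_annotation(
#'   data.frame(gene_id = paste0("g", 1:4), tss = 0:3 * 100, strand = "+"),
#'   1000
#' )
#' rs <- regulon_set(
#'   data.frame(
#'     regulator = c("FIS", "FIS", "FIS", "RpoD", "RpoD", "RpoD"),
#'     target = c("g1", "g2", "g3", "g2", "g3", "g4"),
#'     effect = "+"
#'   ),
#'   class_map = c(FIS = "NAP", RpoD = "sigma"), annotation = ann
#' )
#' build_couplon(rs, "FIS", "RpoD")$members
build_couplon <- function(rs, nap, sigma, check_classes = TRUE) {
  classes <- regulator_classes(rs)
  for (r in c(nap, sigma)) {
    if (!r %in% names(classes)) abort2("unknown regulator: ", r)
  }
  if (check_classes) {
    if (!classes[[nap]] %in% c("NAP", "globalTF")) {
      abort2(nap, " has class ", classes[[nap]],
             " but a NAP or globalTF is required (check_classes = FALSE overrides)")
    }
    if (classes[[sigma]] != "sigma") {
      abort2(sigma, " has class ", classes[[sigma]],
             " but a sigma factor is required (check_classes = FALSE overrides)")
    }
  }
  a <- regulon_members(rs, nap)
  b <- regulon_members(rs, sigma)
  structure(
    list(
      nap_or_tf = nap,
      sigma = sigma,
      members = sort(intersect(a, b)),
      parent_sizes = c(nap_or_tf = length(a), sigma = length(b))
    ),
    class = "couplon"
  )
}

#' @export
print.couplon <- function(x, ...) {
  cat(sprintf(
    "<couplon> %s/%s: %d genes (parents %d and %d)\n",
    x$nap_or_tf, x$sigma, length(x$members),
    x$parent_sizes[["nap_or_tf"]], x$parent_sizes[["sigma"]]
  ))
  invisible(x)
}

#' @export
tidy.couplon <- function(x, ...) {
  tibble(nap_or_tf = x$nap_or_tf, sigma = x$sigma, gene_id = x$members)
}

#' @export
glance.couplon <- function(x, ...) {
  tibble(
    nap_or_tf = x$nap_or_tf,
    sigma = x$sigma,
    n_members = length(x$members),
    parent_nap = x$parent_sizes[["nap_or_tf"]],
    parent_sigma = x$parent_sizes[["sigma"]]
  )
}

#' Couplon size table for a family of regulator pairs
#'
#' Crosses every NAP/global-TF in `naps` with every sigma factor in `sigmas`
#' and reports couplon sizes (long tibble; pivot wide or write as a grid with
#' [write_couplon_table()]). Member lists are kept in a list-column.
#'
#' @inheritParams build_couplon
#' @param naps character vector of NAP/global-TF regulator names.
#' @param sigmas character vector of sigma-factor names.
#' @return A tibble of class `couplon_table` with columns `nap_or_tf`,
#'   `sigma`, `size`, `members` (list-column).
#' @export
couplon_table <- function(rs, naps, sigmas, check_classes = TRUE) {
  missing <- setdiff(c(naps, sigmas), unique(rs$regulator))
  if (length(missing) > 0) {
    abort2("regulator(s) not in regulon set: ", paste(missing, collapse = ", "))
  }
  grid <- tidyr::expand_grid(nap_or_tf = naps, sigma = sigmas)
  cps <- purrr::pmap(grid, function(nap_or_tf, sigma) {
    build_couplon(rs, nap_or_tf, sigma, check_classes = check_classes)
  })
  out <- grid |>
    mutate(
      size = purrr::map_int(cps, ~ length(.x$members)),
      members = purrr::map(cps, "members")
    )
  class(out) <- c("couplon_table", class(tibble()))
  out
}

#' Write a couplon size grid (and member lists) to TSV
#'
#' The grid is `naps x sigmas` with one row per NAP/global-TF. When
#' `members_path` is given, a long TSV of per-couplon member genes is written
#' alongside.
#'
#' @param ct a `couplon_table`.
#' @param path output path for the size grid.
#' @param members_path optional output path for member lists.
#' @return `path`, invisibly.
#' @export
write_couplon_table <- function(ct, path, members_path = NULL) {
  wide <- ct |>
    select("nap_or_tf", "sigma", "size") |>
    tidyr::pivot_wider(names_from = "sigma", values_from = "size")
  readr::write_tsv(wide, path)
  if (!is.null(members_path)) {
    long <- ct |>
      select("nap_or_tf", "sigma", "members") |>
      tidyr::unnest_longer("members", values_to = "gene_id")
    readr::write_tsv(long, members_path)
  }
  invisible(path)
}
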