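#' Construct a regulon set from a regulator-target table
#'
#' A regulon set is the tidy form of a transcriptional regulatory network
#' (TRN): one row per regulator-target edge with the regulator class (NAP,
#' sigma or globalTF) and the effect sign. It is always tied to a genome
#' annotation; edges whose target is absent from the annotation are dropped
#' and counted. Duplicate (regulator, target) pairs with conflicting signs
#' collapse to effect `"dual"`.
#'
#' @param edges data frame with columns `regulator`, `target`, `effect`.
#'   Effects may be spelled `+`/`-`/`+-`/`?` or
#'   `activation`/`repression`/`dual`/`unknown`.
#' @param class_map named character vector (or named list) mapping each
#'   regulator name to one of `"NAP"`, `"sigma"`, `"globalTF"`.
#' @param annotation the `genome_annotation` the targets refer to.
#' @param regulator_genes optional named character vector mapping regulator
#'   names to the gene ids encoding them (used by
#'   [regulator_vs_regulon()]-style analyses).
#' @return A tibble of class `regulon_set` with columns `regulator`,
#'   `regulator_class`, `gene_id`, `effect`, and attributes `annotation`,
#'   `n_dropped` (targets absent from the annotation) and `regulator_genes`.
#' @export
regulon_set <- function(edges, class_map, annotation, regulator_genes = NULL) {
  stopifnot(is.data.frame(edges))
  need <- c("regulator", "target", "effect")
  miss <- setdiff(need, names(edges))
  if (length(miss) > 0) abort2("TRN table is missing column(s): ", paste(miss, collapse = ", "))
  if (!inherits(annotation, "genome_annotation")) {
    abort2("annotation must be a genome_annotation")
  }
  class_map <- unlist(class_map)
  bad_class <- setdiff(unique(class_map), c("NAP", "sigma", "globalTF"))
  if (length(bad_class) > 0) {
    abort2("unknown regulator class(es): ", paste(bad_class, collapse = ", "))
  }

  edges <- as_tibble(edges)
  if (nrow(edges) == 0) {
    warn2("empty TRN: regulon set has no edges")
  }
  edges$regulator <- as.character(edges$regulator)
  edges$target <- as.character(edges$target)
  edges$effect <- normalize_effect(as.character(edges$effect))

  unmapped <- setdiff(unique(edges$regulator), names(class_map))
  if (length(unmapped) > 0) {
    abort2("regulator(s) missing from class map: ", paste(unmapped, collapse = ", "))
  }

  known <- edges$target %in% annotation$gene_id
  n_dropped <- sum(!known)
  if (n_dropped > 0) {
    message(n_dropped, " TRN edge(s) dropped: target absent from annotation")
  }
  edges <- edges[known, , drop = FALSE]

  # conflicting signs for the same regulator-target pair collapse to "dual"
  edges <- edges |>
    group_by(.data$regulator, .data$target) |>
    summarise(
      effect = if (dplyr::n_distinct(.data$effect) > 1) "dual" else .data$effect[1],
      .groups = "drop"
    )

  out <- tibble(
    regulator = edges$regulator,
    regulator_class = unname(class_map[edges$regulator]),
    gene_id = edges$target,
    effect = edges$effect
  ) |>
    arrange(.data$regulator, .data$gene_id)

  structure(
    out,
    annotation = annotation,
    n_dropped = n_dropped,
    regulator_genes = regulator_genes,
    class = c("regulon_set", class(tibble()))
  )
}

normalize_effect <- function(x) {
  out <- dplyr::case_match(
    x,
    c("+", "activation", "activator") ~ "activation",
    c("-", "repression", "repressor") ~ "repression",
    c("+-", "-+", "dual") ~ "dual",
    c("?", "", "unknown") ~ "unknown",
    .default = NA_character_
  )
  if (anyNA(out)) {
    abort2("unrecognised effect value(s): ", paste(unique(x[is.na(out)]), collapse = ", "))
  }
  out
}

#' Read a TRN from TSV
#'
#' Expects a RegulonDB-style tab-separated file with header columns
#' `regulator`, `target`, `effect`. Regulator classes come from a companion
#' YAML/JSON map (`regulator: class`) or a named vector.
#'
#' @param path TSV path.
#' @param class_map named vector, or path to a YAML/JSON file mapping
#'   regulator names to classes.
#' @inheritParams regulon_set
#' @return A `regulon_set`.
#' @export
read_trn <- function(path, class_map, annotation, regulator_genes = NULL) {
  if (!file.exists(path)) abort2("TRN file not found: ", path)
  if (is.character(class_map) && length(class_map) == 1 && file.exists(class_map)) {
    class_map <- unlist(yaml::read_yaml(class_map))
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) <= 1) {
    return(regulon_set(
      tibble(regulator = character(), target = character(), effect = character()),
      class_map, annotation, regulator_genes
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 3)) {
    abort2(
      "malformed TRN row (expected 3 tab-separated fields) at line(s): ",
      paste(which(nf != 3), collapse = ", ")
    )
  }
  header <- fields[[1]]
  if (!identical(tolower(header), c("regulator", "target", "effect"))) {
    abort2("TRN header must be 'regulator<TAB>target<TAB>effect'")
  }
  body <- do.call(rbind, fields[-1])
  edges <- tibble(regulator = body[, 1], target = body[, 2], effect = body[, 3])
  regulon_set(edges, class_map, annotation, regulator_genes)
}

#' Write a TRN to TSV
#'
#' Writes the dialect read back by [read_trn()]; optionally writes the
#' regulator class map alongside as YAML.
#'
#' @param rs a `regulon_set`.
#' @param path TSV output path.
#' @param class_map_path optional path for a YAML regulator->class map.
#' @return `path`, invisibly.
#' @export
write_trn <- function(rs, path, class_map_path = NULL) {
  out <- tibble(
    regulator = rs$regulator,
    target = rs$gene_id,
    effect = rs$effect
  )
  readr::write_tsv(out, path)
  if (!is.null(class_map_path)) {
    yaml::write_yaml(as.list(regulator_classes(rs)), class_map_path)
  }
  invisible(path)
}

#' Regulator classes of a regulon set
#' @param rs a `regulon_set`.
#' @return Named character vector regulator -> class.
#' @export
regulator_classes <- function(rs) {
  u <- distinct(as_tibble(rs)[c("regulator", "regulator_class")])
  setNames(u$regulator_class, u$regulator)
}

#' Member genes of one regulon
#'
#' @param rs a `regulon_set`.
#' @param regulator regulator name.
#' @param effects optional subset of effect signs to keep (e.g.
#'   `"activation"`); by default membership ignores sign.
#' @return Character vector of gene ids.
#' @export
regulon_members <- function(rs, regulator, effects = NULL) {
  if (!regulator %in% rs$regulator) abort2("unknown regulator: ", regulator)
  rows <- rs$regulator == regulator
  if (!is.null(effects)) rows <- rows & rs$effect %in% effects
  sort(unique(rs$gene_id[rows]))
}

#' @export
tidy.regulon_set <- function(x, ...) {
  as_tibble(x) |>
    group_by(.data$regulator, .data$regulator_class) |>
    summarise(n_targets = dplyr::n_distinct(.data$gene_id), .groups = "drop")
}

#' @export
glance.regulon_set <- function(x, ...) {
  tibble(
    n_regulators = dplyr::n_distinct(x$regulator),
    n_edges = nrow(x),
    n_genes = dplyr::n_distinct(x$gene_id),
    n_dropped = attr(x, "n_dropped") %||% 0L
  )
}
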