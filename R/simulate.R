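#' Specification for a synthetic regulon/couplon dataset
#'
#' Describes a synthetic circular genome, regulatory network and growth-phase
#' expression time-course with planted structure: an OriC->Ter GC gradient
#' (linear in circular distance from the origin, symmetric on both
#' replichores), regulons whose members cluster within +-100 kb of a
#' chromosomal centre, controlled couplon overlaps between NAP/global-TF and
#' sigma regulons, and one dominant temporal program (early / mid / late /
#' flat peak over the sampled growth phases) per gene plus Gaussian noise.
#'
#' The defaults emulate an E. coli-like chromosome: 4,000 genes on 4.6 Mb,
#' promoter GC falling from 0.56 at OriC (position 0) to 0.48 at Ter, samples
#' at 60, 120, 180, 300 and 420 minutes after inoculation, and a regulator
#' roster of four NAPs (FIS, H-NS, Lrp, IHF), two global TFs (CRP, Fnr) and
#' five sigma factors (RpoD plus the alternative factors RpoS, RpoN, RpoH,
#' RpoE). The late program declines after its 300-minute peak — the planted
#' analogue of stationary-phase repression of the RpoS axis by FIS — and the
#' `fis_mutant` condition of [generate_timecourse()] removes that decline.
#'
#' @param n_genes number of genes (default 4,000).
#' @param chromosome_length bp (default 4,600,000).
#' @param gc_ori,gc_ter promoter GC fraction at the origin and terminus
#'   (defaults 0.56 and 0.48).
#' @param timepoints sampling times in minutes (default
#'   `c(60, 120, 180, 300, 420)`).
#' @param noise_sd expression noise SD as a fraction of each gene's program
#'   range (default 0.2).
#' @param baseline_scale mean baseline expression level (default 100).
#' @param regulators data frame with columns `name`, `class`, `size`,
#'   `center` (bp), `concentration` (fraction of members within +-100 kb of
#'   the centre) and `program` (`"early"`, `"mid"`, `"late"` or `"flat"`).
#' @param overlaps data frame with columns `nap`, `sigma`, `fraction`: the
#'   fraction of the NAP/global-TF regulon shared with that sigma regulon.
#' @param programs named list of program shapes (one value per timepoint).
#' @param exact_overlap draw shared members so couplon sizes match the
#'   configured fractions exactly (default TRUE); non-shared NAP members are
#'   then kept out of all sigma regulons.
#' @param couplon_follow_sigma genes in a sigma regulon follow the sigma
#'   parent's temporal program even when also in a NAP regulon (default
#'   TRUE).
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(n_genes = 4000,
                     chromosome_length = 4.6e6,
                     gc_ori = 0.56,
                     gc_ter = 0.48,
                     timepoints = c(60, 120, 180, 300, 420),
                     noise_sd = 0.2,
                     baseline_scale = 100,
                     regulators = default_regulators(),
                     overlaps = default_overlaps(),
                     programs = default_programs(length(timepoints)),
                     exact_overlap = TRUE,
                     couplon_follow_sigma = TRUE) {
  spec <- list(
    n_genes = n_genes,
    chromosome_length = chromosome_length,
    gc_ori = gc_ori,
    gc_ter = gc_ter,
    timepoints = timepoints,
    noise_sd = noise_sd,
    baseline_scale = baseline_scale,
    regulators = as_tibble(regulators),
    overlaps = as_tibble(overlaps),
    programs = programs,
    exact_overlap = exact_overlap,
    couplon_follow_sigma = couplon_follow_sigma
  )
  validate_sim_spec(spec)
  structure(spec, class = "sim_spec")
}

validate_sim_spec <- function(spec) {
  with(spec, {
    stopifnot(
      n_genes > 0, chromosome_length > 0,
      gc_ori >= 0, gc_ori <= 1, gc_ter >= 0, gc_ter <= 1,
      length(timepoints) >= 2, all(diff(timepoints) > 0),
      noise_sd >= 0, baseline_scale > 0
    )
    if (n_genes > chromosome_length / 100) {
      abort2("unrealistic gene density: n_genes > chromosome_length / 100")
    }
    need <- c("name", "class", "size", "center", "concentration", "program")
    miss <- setdiff(need, names(regulators))
    if (length(miss) > 0) abort2("regulators table missing: ", paste(miss, collapse = ", "))
    if (any(regulators$size > n_genes)) abort2("regulon size exceeds n_genes")
    if (any(regulators$concentration < 0 | regulators$concentration > 1)) {
      abort2("spatial concentration must be in [0, 1]")
    }
    if (!all(regulators$program %in% names(programs))) {
      abort2("unknown temporal program in regulators table")
    }
    if (any(vapply(programs, length, integer(1)) != length(timepoints))) {
      abort2("every program must have one value per timepoint")
    }
    if (nrow(overlaps) > 0) {
      if (any(overlaps$fraction < 0 | overlaps$fraction > 1)) {
        abort2("overlap fractions must be in [0, 1]")
      }
      if (!all(overlaps$nap %in% regulators$name) ||
          !all(overlaps$sigma %in% regulators$name)) {
        abort2("overlaps reference unknown regulators")
      }
    }
  })
  invisible(spec)
}

#' @rdname sim_spec
#' @export
default_regulators <- function() {
  tibble(
    name = c("FIS", "H-NS", "Lrp", "IHF", "CRP", "Fnr",
             "RpoD", "RpoS", "RpoN", "RpoH", "RpoE"),
    class = c(rep("NAP", 4), rep("globalTF", 2), rep("sigma", 5)),
    size = c(230, 200, 180, 220, 400, 250, 800, 300, 150, 100, 100),
    center = c(0.92e6, 2.76e6, 3.68e6, 1.38e6, 0.46e6, 2.30e6,
               0.10e6, 2.30e6, 3.20e6, 0.70e6, 4.10e6),
    concentration = c(0.4, 0.4, 0.4, 0.4, 0.2, 0.2,
                      0.1, 0.3, 0.3, 0.3, 0.3),
    program = c("early", "mid", "mid", "mid", "late", "mid",
                "early", "late", "mid", "early", "early")
  )
}

#' @rdname sim_spec
#' @export
default_overlaps <- function() {
  naps <- c("FIS", "H-NS", "Lrp", "IHF", "CRP", "Fnr")
  bind_rows(
    tibble(nap = naps, sigma = "RpoD", fraction = 0.25),
    tidyr::expand_grid(nap = naps, sigma = c("RpoS", "RpoN", "RpoH", "RpoE")) |>
      mutate(fraction = 0.10)
  )
}

#' @rdname sim_spec
#' @param n_timepoints number of sampled timepoints.
#' @export
default_programs <- function(n_timepoints = 5) {
  p <- list(
    early = c(1.00, 0.85, 0.50, 0.20, 0.10),
    mid = c(0.20, 0.70, 1.00, 0.50, 0.25),
    late = c(0.10, 0.20, 0.60, 1.00, 0.30),
    late_derepressed = c(0.10, 0.20, 0.60, 0.95, 1.00),
    flat = rep(0.5, 5)
  )
  if (n_timepoints != 5) {
    # resample each shape onto the requested number of timepoints
    p <- lapply(p, function(v) {
      stats::approx(seq_along(v), v, n = n_timepoints)$y
    })
  }
  p
}

#' Generate a synthetic circular genome with an OriC->Ter GC gradient
#'
#' TSS positions are uniform on the circle (distinct per gene); each base is
#' drawn i.i.d. at the local GC probability, which falls linearly with
#' circular distance from the origin, from `gc_ori` at position 0 (OriC) to
#' `gc_ter` at `length/2` (Ter), symmetrically on both replichores.
#'
#' @param spec a `sim_spec`.
#' @param seed RNG seed (same seed, same genome).
#' @return A list with `annotation` (a `genome_annotation`) and `genome`
#'   (a `DNAStringSet` named `chr`).
#' @export
generate_genome <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  len <- spec$chromosome_length
  with_seed_if(seed, {
    tss <- sort(sample.int(len, spec$n_genes) - 1)
    strand <- sample(c("+", "-"), spec$n_genes, replace = TRUE)
    ann <- genome_annotation(
      tibble(
        gene_id = sprintf("g%04d", seq_len(spec$n_genes)),
        tss = tss,
        strand = strand
      ),
      chromosome_length = len
    )
    pos <- seq_len(len) - 1
    d <- pmin(pos, len - pos) # circular distance to OriC at 0
    gc_local <- spec$gc_ori + (spec$gc_ter - spec$gc_ori) * d / (len / 2)
    is_gc <- runif(len) < gc_local
    pick <- runif(len) < 0.5
    bases <- ifelse(is_gc, ifelse(pick, "G", "C"), ifelse(pick, "A", "T"))
    genome <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
    names(genome) <- "chr"
    list(annotation = ann, genome = genome)
  })
}

#' Generate a synthetic TRN with planted clustering and couplon overlaps
#'
#' Sigma regulons are drawn first: a `concentration` fraction of each
#' regulon's members comes from within +-100 kb of its chromosomal centre and
#' the rest uniformly from the remaining genes. NAP/global-TF regulons then
#' share the configured fraction of their members with each sigma regulon
#' (sampled from that sigma's members); with `exact_overlap = TRUE` the
#' remaining members are drawn from genes outside all sigma regulons, so each
#' couplon size equals `round(fraction * size)` exactly. Every regulator is
#' also assigned a gene that encodes it (recorded in the `regulator_genes`
#' attribute) whose expression follows the regulon's program.
#'
#' @inheritParams generate_genome
#' @param annotation the annotation from [generate_genome()].
#' @return A `regulon_set`.
#' @export
generate_trn <- function(spec, annotation, seed = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  regs <- spec$regulators
  len <- chromosome_length(annotation)
  ids <- annotation$gene_id
  tss <- setNames(annotation$tss, ids)

  with_seed_if(seed, {
    draw_spatial <- function(size, center, concentration, pool) {
      near <- pool[circ_dist(tss[pool], center, len) <= 1e5]
      n_near <- min(round(size * concentration), length(near), size)
      picked <- if (n_near > 0) sample(near, n_near) else character(0)
      rest_pool <- setdiff(pool, picked)
      n_rest <- size - n_near
      if (n_rest > length(rest_pool)) abort2("regulon size infeasible")
      c(picked, if (n_rest > 0) sample(rest_pool, n_rest) else character(0))
    }

    members <- list()
    sig_names <- regs$name[regs$class == "sigma"]
    for (i in which(regs$class == "sigma")) {
      members[[regs$name[i]]] <- draw_spatial(
        regs$size[i], regs$center[i], regs$concentration[i], ids
      )
    }
    in_sigma <- unique(unlist(members[sig_names]))

    for (i in which(regs$class != "sigma")) {
      nm <- regs$name[i]
      size <- regs$size[i]
      ov <- spec$overlaps[spec$overlaps$nap == nm, , drop = FALSE]
      shared <- character(0)
      if (nrow(ov) > 0) {
        k <- round(ov$fraction * size)
        if (sum(k) > size) {
          abort2("infeasible overlaps for ", nm, ": shared fractions exceed 1")
        }
        sig_tab <- table(unlist(members[sig_names]))
        multi_sigma <- names(sig_tab)[sig_tab > 1]
        for (j in seq_len(nrow(ov))) {
          pool <- setdiff(members[[ov$sigma[j]]], shared)
          # in exact mode a shared gene must sit in exactly one sigma regulon,
          # otherwise it would inflate another couplon
          if (spec$exact_overlap) pool <- setdiff(pool, multi_sigma)
          if (k[j] > length(pool)) {
            abort2("infeasible overlap between ", nm, " and ", ov$sigma[j],
                   ": sigma regulon too small")
          }
          shared <- c(shared, sample(pool, k[j]))
        }
      }
      own_pool <- if (spec$exact_overlap) setdiff(ids, in_sigma) else setdiff(ids, shared)
      own <- draw_spatial(size - length(shared), regs$center[i],
                          regs$concentration[i], own_pool)
      members[[nm]] <- c(shared, own)
    }

    # one gene encodes each regulator; keep them out of their own regulon so
    # regulator-vs-regulon correlations compare distinct quantities
    free <- setdiff(ids, unique(unlist(members)))
    if (length(free) < nrow(regs)) free <- ids
    reg_genes <- setNames(sample(free, nrow(regs)), regs$name)

    edges <- purrr::imap(members, function(gs, nm) {
      tibble(
        regulator = nm,
        target = gs,
        effect = sample(c("+", "-"), length(gs), replace = TRUE, prob = c(0.8, 0.2))
      )
    }) |> bind_rows()

    regulon_set(
      edges,
      class_map = setNames(regs$class, regs$name),
      annotation = annotation,
      regulator_genes = reg_genes
    )
  })
}

#' Generate a synthetic growth-phase expression time-course
#'
#' Every gene follows one dominant temporal program: members of a sigma
#' regulon follow the sigma factor's program (when `couplon_follow_sigma` is
#' set, mirroring the observation that couplon expression tracks the sigma
#' parent), remaining regulon members follow their regulator's program,
#' regulator-encoding genes follow their own regulon's program, and
#' unregulated genes are flat. Values are
#' `baseline_g * program(t) + N(0, noise_sd * baseline_g * range(program))`,
#' clipped at 0. Under `condition = "fis_mutant"` the planted stationary-phase
#' repression of the late program is removed: late-program genes switch to a
#' derepressed variant that keeps rising instead of declining after the
#' 300-minute peak.
#'
#' @inheritParams generate_genome
#' @param rs the `regulon_set` from [generate_trn()].
#' @param condition `"wt"` or `"fis_mutant"`.
#' @return An `expression_timecourse`.
#' @export
generate_timecourse <- function(spec, rs, seed = NULL,
                                condition = c("wt", "fis_mutant")) {
  stopifnot(inherits(spec, "sim_spec"))
  condition <- match.arg(condition)
  if (spec$noise_sd < 0) abort2("noise_sd must be non-negative")
  ann <- attr(rs, "annotation")
  ids <- ann$gene_id
  regs <- spec$regulators
  programs <- spec$programs

  prog_of_reg <- setNames(regs$program, regs$name)
  if (condition == "fis_mutant") {
    prog_of_reg[prog_of_reg == "late"] <- "late_derepressed"
  }

  assignment <- setNames(rep("flat", length(ids)), ids)
  order_classes <- if (spec$couplon_follow_sigma) {
    c("NAP", "globalTF", "sigma") # sigma assigned last, wins
  } else {
    c("sigma", "NAP", "globalTF")
  }
  for (cl in order_classes) {
    for (nm in regs$name[regs$class == cl]) {
      if (!nm %in% rs$regulator) next
      assignment[regulon_members(rs, nm)] <- prog_of_reg[[nm]]
    }
  }
  reg_genes <- attr(rs, "regulator_genes")
  if (!is.null(reg_genes)) {
    assignment[reg_genes] <- prog_of_reg[names(reg_genes)]
  }

  tpn <- length(spec$timepoints)
  with_seed_if(seed, {
    baseline <- spec$baseline_scale * runif(length(ids), 0.5, 1.5)
    pm <- do.call(rbind, programs[assignment]) # genes x timepoints
    rng <- apply(pm, 1, function(p) max(p) - min(p))
    # flat genes still fluctuate: scale their noise by the program level
    rng <- ifelse(rng > 0, rng, vapply(assignment, function(a) mean(programs[[a]]), 1))
    values <- baseline * pm +
      matrix(rnorm(length(ids) * tpn, sd = spec$noise_sd * baseline * rng),
             nrow = length(ids))
    values[values < 0] <- 0
    df <- dplyr::bind_cols(
      tibble(gene_id = ids),
      as_tibble(values, .name_repair = ~ as.character(spec$timepoints))
    )
    as_timecourse(df)
  })
}

#' Write a complete synthetic dataset to disk
#'
#' Generates genome, TRN and wild-type time-course under one seed and writes
#' the exact dialects the loaders read: FASTA, annotation TSV, TRN TSV with a
#' YAML class map, and expression TSV. A `fis_mutant` time-course is written
#' alongside when `conditions` includes it.
#'
#' @inheritParams generate_genome
#' @param dir output directory (created if needed).
#' @param conditions time-course conditions to write (default both).
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
simulate_dataset <- function(spec, dir, seed = NULL,
                             conditions = c("wt", "fis_mutant")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(seed)) NULL else as.integer(seed)
  gen <- generate_genome(spec, seed = seed)
  rs <- generate_trn(spec, gen$annotation, seed = if (is.null(seed)) NULL else seed + 1L)
  paths <- list(
    fasta = file.path(dir, "genome.fasta"),
    annotation = file.path(dir, "annotation.tsv"),
    trn = file.path(dir, "trn.tsv"),
    class_map = file.path(dir, "regulator_classes.yaml"),
    regulator_genes = file.path(dir, "regulator_genes.yaml")
  )
  Biostrings::writeXStringSet(gen$genome, paths$fasta)
  write_annotation(gen$annotation, paths$annotation)
  write_trn(rs, paths$trn, class_map_path = paths$class_map)
  yaml::write_yaml(as.list(attr(rs, "regulator_genes")), paths$regulator_genes)
  tcs <- list()
  for (i in seq_along(conditions)) {
    cond <- conditions[i]
    tc <- generate_timecourse(
      spec, rs,
      seed = if (is.null(seed)) NULL else seed + 1L + i,
      condition = cond
    )
    p <- file.path(dir, paste0("expression_", cond, ".tsv"))
    write_timecourse(tc, p)
    paths[[paste0("expression_", cond)]] <- p
    tcs[[cond]] <- tc
  }
  invisible(list(
    annotation = gen$annotation, genome = gen$genome, regulon_set = rs,
    timecourses = tcs, paths = paths, spec = spec, seed = seed
  ))
}
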