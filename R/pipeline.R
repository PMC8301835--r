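#' Run the full regulon/couplon analysis pipeline
#'
#' Orchestrates an end-to-end run: obtain inputs (either simulate a dataset
#' from a [sim_spec()] or load annotation/TRN/expression/FASTA files), build
#' the couplon table, compute spatial Z-profiles and the couplon-vs-parent
#' spatial correlations, compute temporal profiles with remapping envelopes
#' and the couplon-vs-parent temporal correlations plus regulator-gene
#' correlations, and profile promoter GC content. Every stage writes TSV/JSON
#' outputs under `out_dir` and the run is summarised in a machine-readable
#' manifest (`manifest.json`) recording package version, seed, parameters,
#' input checksums, warning counts and the files written. Missing optional
#' inputs degrade explicitly: without expression data the temporal stage is
#' skipped and logged; without a FASTA the GC stage is skipped and logged.
#'
#' @param config a named list (or path to a YAML file) with entries:
#'   * `seed` (required for any stochastic stage),
#'   * `out_dir` output directory,
#'   * either `simulation` (list of [sim_spec()] arguments, or `TRUE` for the
#'     defaults) or `inputs` (list with `annotation`, `trn`, `class_map`, and
#'     optionally `expression`, `fasta`, `regulator_genes`),
#'   * optional `naps` / `sigmas` (regulator names; default: every
#'     NAP/globalTF and every sigma in the TRN),
#'   * optional stage parameter lists `spatial` (`window`, `step`,
#'     `n_samples`, `method`, `threshold`), `temporal` (`remap_fraction`,
#'     `n_reps`), `gc` (`upstream`, `downstream`, `smoothing`).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort2("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  out_dir <- config$out_dir %||% abort2("config needs an out_dir")
  seed <- config$seed %||% abort2("config needs a seed (stochastic stages)")
  seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  warnings_log <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    warnings_log <<- c(warnings_log, msg)
    message("[couplonscan] ", msg)
  }
  outputs <- character(0)
  emit <- function(path) {
    outputs <<- c(outputs, path)
    path
  }

  sp <- config$spatial %||% list()
  window <- sp$window %||% 1e5
  step <- sp$step %||% 1e4
  n_samples <- sp$n_samples %||% 10000
  sp_method <- sp$method %||% "montecarlo"
  threshold <- sp$threshold %||% 2
  tp <- config$temporal %||% list()
  remap_fraction <- tp$remap_fraction %||% 0.10
  n_reps <- tp$n_reps %||% 100
  gcp <- config$gc %||% list()
  upstream <- gcp$upstream %||% 300
  downstream <- gcp$downstream %||% 200
  smoothing <- gcp$smoothing %||% 21

  checksums <- list()

  # ---- stage 0: inputs -------------------------------------------------
  if (!is.null(config$simulation)) {
    spec_args <- if (isTRUE(config$simulation)) list() else config$simulation
    spec <- do.call(sim_spec, spec_args)
    sim <- simulate_dataset(spec, file.path(out_dir, "simulated"), seed = seed)
    annotation <- sim$annotation
    rs <- sim$regulon_set
    tc <- sim$timecourses$wt
    genome <- sim$genome
    for (p in unlist(sim$paths)) emit(p)
  } else {
    inp <- config$inputs %||% abort2("config needs either simulation or inputs")
    for (key in c("annotation", "trn", "class_map")) {
      if (is.null(inp[[key]])) abort2("inputs must name a ", key, " file")
    }
    for (key in c("annotation", "trn", "class_map")) {
      if (!file.exists(inp[[key]])) abort2("input file not found: ", inp[[key]])
    }
    annotation <- read_annotation(inp$annotation)
    reg_genes <- if (!is.null(inp$regulator_genes)) {
      unlist(yaml::read_yaml(inp$regulator_genes))
    } else {
      NULL
    }
    rs <- read_trn(inp$trn, inp$class_map, annotation, regulator_genes = reg_genes)
    tc <- NULL
    if (!is.null(inp$expression)) {
      tc <- read_timecourse(inp$expression)
    }
    genome <- if (!is.null(inp$fasta)) read_genome(inp$fasta) else NULL
    for (key in c("annotation", "trn", "class_map", "expression", "fasta")) {
      if (!is.null(inp[[key]])) {
        checksums[[key]] <- unname(tools::md5sum(inp[[key]]))
      }
    }
  }

  classes <- regulator_classes(rs)
  naps <- config$naps %||% names(classes)[classes %in% c("NAP", "globalTF")]
  sigmas <- config$sigmas %||% names(classes)[classes == "sigma"]

  # ---- stage 1: couplons ----------------------------------------------
  ct <- couplon_table(rs, naps, sigmas)
  write_couplon_table(
    ct,
    emit(file.path(out_dir, "couplon_sizes.tsv")),
    members_path = emit(file.path(out_dir, "couplon_members.tsv"))
  )

  # ---- stage 2: spatial enrichment ------------------------------------
  grid <- make_grid(chromosome_length(annotation), window, step)
  sets <- c(
    setNames(lapply(c(naps, sigmas), function(r) regulon_members(rs, r)),
             c(naps, sigmas)),
    setNames(
      purrr::map(seq_len(nrow(ct)), ~ ct$members[[.x]]),
      paste0(ct$nap_or_tf, "_", ct$sigma)
    )
  )
  sets <- sets[vapply(sets, length, integer(1)) > 0]
  zps <- purrr::imap(sets, function(gs, nm) {
    z_profile(annotation, gs, grid,
              threshold = threshold, n_samples = n_samples,
              seed = seed, method = sp_method, set_name = nm)
  })
  dir.create(file.path(out_dir, "spatial"), showWarnings = FALSE)
  for (nm in names(zps)) {
    write_zprofile(
      zps[[nm]],
      emit(file.path(out_dir, "spatial", paste0(nm, ".tsv"))),
      bed_path = emit(file.path(out_dir, "spatial", paste0(nm, ".bed")))
    )
  }
  spatial_cor <- purrr::pmap(ct[c("nap_or_tf", "sigma", "size")],
    function(nap_or_tf, sigma, size) {
      cp_name <- paste0(nap_or_tf, "_", sigma)
      if (size == 0 || !cp_name %in% names(zps)) {
        return(tibble(couplon = cp_name, vs_nap = NA_real_, vs_sigma = NA_real_))
      }
      tibble(
        couplon = cp_name,
        vs_nap = spatial_correlation(zps[[cp_name]], zps[[nap_or_tf]])$r,
        vs_sigma = spatial_correlation(zps[[cp_name]], zps[[sigma]])$r
      )
    }) |> bind_rows()
  jsonlite::write_json(
    spatial_cor,
    emit(file.path(out_dir, "spatial_correlations.json")),
    auto_unbox = TRUE, digits = NA, na = "null"
  )

  # ---- stage 3: temporal profiles -------------------------------------
  if (is.null(tc)) {
    note("temporal stage skipped: no expression input")
    temporal_cor <- NULL
  } else {
    dir.create(file.path(out_dir, "temporal"), showWarnings = FALSE)
    profs <- list()
    for (nm in names(sets)) {
      pr <- tryCatch(
        remap_envelope(tc, sets[[nm]], fraction = remap_fraction,
                       n_reps = n_reps, seed = seed, set_name = nm),
        error = function(e) {
          note("temporal profile skipped for ", nm, ": ", conditionMessage(e))
          NULL
        }
      )
      if (is.null(pr)) next
      profs[[nm]] <- pr
      write_profile(pr, emit(file.path(out_dir, "temporal", paste0(nm, ".tsv"))))
      emit(file.path(out_dir, "temporal", paste0(nm, ".tsv.json")))
    }
    temporal_cor <- purrr::pmap(ct[c("nap_or_tf", "sigma", "size")],
      function(nap_or_tf, sigma, size) {
        cp_name <- paste0(nap_or_tf, "_", sigma)
        ok <- !is.null(profs[[cp_name]]) && !is.null(profs[[nap_or_tf]]) &&
          !is.null(profs[[sigma]])
        tibble(
          couplon = cp_name,
          vs_nap = if (ok) as.numeric(profile_correlation(profs[[cp_name]], profs[[nap_or_tf]])) else NA_real_,
          vs_sigma = if (ok) as.numeric(profile_correlation(profs[[cp_name]], profs[[sigma]])) else NA_real_
        )
      }) |> bind_rows()
    reg_genes <- attr(rs, "regulator_genes")
    if (!is.null(reg_genes)) {
      reg_cor <- purrr::imap(
        reg_genes[names(reg_genes) %in% names(sets)],
        function(g, nm) {
          r <- tryCatch(
            as.numeric(regulator_vs_regulon(tc, g, sets[[nm]])),
            error = function(e) NA_real_
          )
          tibble(regulator = nm, gene = g, r = r)
        }
      ) |> bind_rows()
    } else {
      reg_cor <- NULL
    }
    jsonlite::write_json(
      list(couplon_vs_parents = temporal_cor, regulator_vs_regulon = reg_cor),
      emit(file.path(out_dir, "temporal_correlations.json")),
      auto_unbox = TRUE, digits = NA, na = "null"
    )
  }

  # ---- stage 4: promoter GC -------------------------------------------
  if (is.null(genome)) {
    note("GC stage skipped: no FASTA input")
  } else {
    all_ctx <- extract_contexts(genome, annotation, upstream, downstream)
    gp_all <- gc_profile(all_ctx, smoothing)
    gc_tabs <- purrr::imap(sets, function(gs, nm) {
      p <- gc_profile(
        extract_contexts(genome, annotation, upstream, downstream, gene_set = gs),
        smoothing
      )
      tibble(position = p$position, set = nm, gc = p$gc, n_used = p$n_used)
    })
    gc_out <- bind_rows(
      tibble(position = gp_all$position, set = "all_genes",
             gc = gp_all$gc, n_used = gp_all$n_used),
      bind_rows(gc_tabs)
    )
    readr::write_tsv(gc_out, emit(file.path(out_dir, "gc_profiles.tsv")))
  }

  manifest <- list(
    package = "couplonscan",
    version = as.character(utils::packageVersion("couplonscan")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    parameters = list(
      spatial = list(window = window, step = step, n_samples = n_samples,
                     method = sp_method, threshold = threshold),
      temporal = list(remap_fraction = remap_fraction, n_reps = n_reps),
      gc = list(upstream = upstream, downstream = downstream,
                smoothing = smoothing),
      naps = naps, sigmas = sigmas
    ),
    input_checksums = checksums,
    warnings = as.list(warnings_log),
    n_warnings = length(warnings_log),
    outputs = as.list(sort(unique(outputs)))
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  invisible(manifest)
}
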