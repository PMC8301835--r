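# Fixtures are built in code: small annotations, time-courses and simulation
# specs reused across test files.

tiny_annotation <- function(n = 20, len = 10000, strand = "+") {
  genome_annotation(
    data.frame(
      gene_id = sprintf("g%02d", seq_len(n)),
      tss = floor(seq(0, len - len / n, length.out = n)),
      strand = strand
    ),
    chromosome_length = len
  )
}

random_annotation <- function(n, len, seed = NULL) {
  draw <- function() {
    genome_annotation(
      data.frame(
        gene_id = sprintf("g%04d", seq_len(n)),
        tss = sort(sample.int(len, n) - 1),
        strand = sample(c("+", "-"), n, replace = TRUE)
      ),
      chromosome_length = len
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

tiny_timecourse <- function(values, gene_ids = NULL,
                            times = c(60, 120, 180, 300, 420)) {
  m <- matrix(values, ncol = length(times), byrow = TRUE)
  ids <- gene_ids %||% sprintf("g%02d", seq_len(nrow(m)))
  df <- data.frame(gene_id = ids, m, check.names = FALSE)
  names(df) <- c("gene_id", as.character(times))
  as_timecourse(df)
}

# timecourse where each gene in `sets` follows its set's program plus noise
program_timecourse <- function(sets, programs, n_extra = 0, noise_sd = 0,
                               times = c(60, 120, 180, 300, 420), seed = 1) {
  withr::with_seed(seed, {
    rows <- list()
    for (nm in names(sets)) {
      p <- programs[[nm]]
      for (g in sets[[nm]]) {
        noise <- rnorm(length(p), sd = noise_sd * (max(p) - min(p)))
        rows[[g]] <- pmax(p + noise, 0)
      }
    }
    if (n_extra > 0) {
      for (i in seq_len(n_extra)) {
        rows[[sprintf("x%03d", i)]] <- pmax(0.5 + rnorm(length(times), sd = 0.1), 0)
      }
    }
    m <- do.call(rbind, rows)
    df <- data.frame(gene_id = names(rows), m, check.names = FALSE)
    names(df) <- c("gene_id", as.character(times))
    as_timecourse(df)
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# a deliberately small simulation spec for fast end-to-end tests
small_sim_spec <- function(...) {
  args <- list(
    n_genes = 400,
    chromosome_length = 4e5,
    regulators = tibble::tibble(
      name = c("FIS", "RpoD", "RpoS"),
      class = c("NAP", "sigma", "sigma"),
      size = c(60, 120, 50),
      center = c(1e5, 0, 2e5),
      concentration = c(0.5, 0.1, 0.4),
      program = c("early", "early", "late")
    ),
    overlaps = tibble::tibble(
      nap = c("FIS", "FIS"), sigma = c("RpoD", "RpoS"), fraction = c(0.3, 0.2)
    )
  )
  do.call(sim_spec, utils::modifyList(args, list(...)))
}
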