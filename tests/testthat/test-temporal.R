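test_that("unit normalisation maps range to [0,1] and flags constants", {
  expect_equal(normalize_unit(c(2, 4, 6, 4, 2)), c(0, 0.5, 1, 0.5, 0))
  expect_warning(out <- normalize_unit(c(3, 3, 3, 3, 3)), "constant")
  expect_true(all(is.na(out)))
  expect_error(normalize_unit(5), "at least 2")
})

test_that("unit normalisation is invariant to positive affine rescaling", {
  withr::with_seed(7, {
    for (i in 1:1000) {
      x <- rnorm(5)
      if (max(x) == min(x)) next
      a <- runif(1, 0.01, 100)
      b <- rnorm(1, sd = 10)
      expect_equal(normalize_unit(a * x + b), normalize_unit(x))
    }
  })
})

test_that("set profiles average per-gene normalised patterns then rescale", {
  # all genes share one pattern -> profile is that pattern normalised,
  # and the pre-rescale extremes are exactly 0 and 1
  p <- c(2, 4, 6, 4, 2)
  tc <- tiny_timecourse(rep(p, 3) * rep(c(1, 10, 100), each = 5))
  prof <- set_profile(tc, tc$gene_id)
  expect_equal(prof$value, c(0, 0.5, 1, 0.5, 0))
  expect_equal(attr(prof, "pre_norm_min"), 0)
  expect_equal(attr(prof, "pre_norm_max"), 1)
  expect_equal(attr(prof, "n_genes_used"), 3)

  # two mirror genes average to a constant: degenerate profile at 0.5
  tc2 <- tiny_timecourse(c(0, 1, 0, 1, 0,
                           1, 0, 1, 0, 1))
  expect_warning(prof2 <- set_profile(tc2, tc2$gene_id), "degenerate")
  expect_equal(prof2$value, rep(0.5, 5))
  expect_true(attr(prof2, "degenerate"))
  expect_equal(attr(prof2, "pre_norm_min"), attr(prof2, "pre_norm_max"))

  # constant genes are excluded and counted, not flattened into the average
  tc3 <- tiny_timecourse(c(2, 4, 6, 4, 2,
                           5, 5, 5, 5, 5))
  prof3 <- set_profile(tc3, tc3$gene_id)
  expect_equal(attr(prof3, "n_genes_used"), 1)
  expect_equal(attr(prof3, "n_excluded"), 1)
  expect_equal(prof3$value, c(0, 0.5, 1, 0.5, 0))

  expect_error(set_profile(tc3, "g02"), "no usable genes")
})

test_that("non-degenerate profiles attain exactly 0 and 1", {
  withr::with_seed(19, {
    for (i in 1:50) {
      tc <- tiny_timecourse(pmax(rnorm(5 * 8, mean = 5), 0))
      prof <- set_profile(tc, sample(tc$gene_id, 4))
      if (!attr(prof, "degenerate")) {
        expect_equal(min(prof$value), 0)
        expect_equal(max(prof$value), 1)
      }
    }
  })
})

test_that("set profiles are invariant to per-gene positive affine rescaling", {
  withr::with_seed(29, {
    tc <- tiny_timecourse(pmax(rnorm(5 * 10, mean = 5), 0.1))
    m <- as.matrix(tibble::as_tibble(tc)[, -1])
    a <- runif(10, 0.1, 50)
    b <- runif(10, 0, 20)
    scaled <- tiny_timecourse(as.vector(t(m * a + b)), gene_ids = tc$gene_id)
    p1 <- set_profile(tc, tc$gene_id)
    p2 <- set_profile(scaled, tc$gene_id)
    expect_equal(p1$value, p2$value)
  })
})

test_that("a planted program is recovered from noisy member genes", {
  program <- c(0.1, 0.4, 1.0, 0.6, 0.2)
  rs <- lapply(1:10, function(seed) {
    tc <- program_timecourse(
      list(reg = sprintf("r%02d", 1:50)),
      list(reg = program),
      noise_sd = 0.2, seed = seed
    )
    prof <- set_profile(tc, sprintf("r%02d", 1:50))
    cor(prof$value, program)
  })
  expect_true(all(unlist(rs) > 0.95))
})

test_that("profile correlation is symmetric with fixed points at +-1", {
  tc <- tiny_timecourse(c(1, 2, 3, 4, 5,
                          5, 4, 3, 2, 1,
                          2, 5, 3, 1, 4))
  p <- set_profile(tc, "g01")
  q <- set_profile(tc, "g02")
  w <- set_profile(tc, "g03")
  expect_equal(as.numeric(profile_correlation(p, p)), 1.0)
  expect_equal(as.numeric(profile_correlation(p, q)), -1.0)
  expect_equal(
    as.numeric(profile_correlation(p, w)),
    as.numeric(profile_correlation(w, p))
  )
  expect_equal(attr(profile_correlation(p, q), "n"), 5)

  bad <- tiny_timecourse(c(1, 2, 3), times = c(60, 120, 180))
  expect_error(profile_correlation(p, set_profile(bad, "g01")), "timepoints")
})

test_that("regulator expression correlates with its regulon as planted", {
  members <- sprintf("m%02d", 1:20)
  program <- c(0.1, 0.3, 1.0, 0.5, 0.2)

  # regulator identical to all member patterns -> r = 1
  tc <- program_timecourse(
    list(set = c("reg", members)),
    list(set = program),
    noise_sd = 0
  )
  expect_equal(as.numeric(regulator_vs_regulon(tc, "reg", members)), 1.0)

  # regulator mirroring the regulon program -> r = -1
  tc2 <- program_timecourse(
    list(reg = "reg", set = members),
    list(reg = 1 - program, set = program),
    noise_sd = 0
  )
  expect_equal(as.numeric(regulator_vs_regulon(tc2, "reg", members)), -1.0)

  # noisy driving regulator stays strongly correlated
  tc3 <- program_timecourse(
    list(set = c("reg", members)),
    list(set = program),
    noise_sd = 0.1, seed = 5
  )
  expect_gt(as.numeric(regulator_vs_regulon(tc3, "reg", members)), 0.9)

  expect_error(regulator_vs_regulon(tc, "absent", members), "absent")
})

test_that("remapping envelopes vanish when nothing can change", {
  members <- sprintf("m%02d", 1:10)
  tc <- program_timecourse(
    list(set = members),
    list(set = c(0.1, 0.5, 1.0, 0.4, 0.2)),
    n_extra = 30, noise_sd = 0.3, seed = 2
  )
  # fraction 0 -> zero envelope with a warning
  expect_warning(
    env0 <- remap_envelope(tc, members, fraction = 0, n_reps = 20, seed = 1),
    "identically zero"
  )
  expect_equal(env0$envelope_sd, rep(0, 5))

  # every gene in the genome shares one pattern -> zero envelope at any fraction
  p <- c(1, 3, 7, 4, 2)
  tc_same <- tiny_timecourse(rep(p, 40) * rep(seq(0.5, 4, length.out = 40), each = 5))
  env1 <- remap_envelope(tc_same, tc_same$gene_id[1:10], fraction = 0.5,
                         n_reps = 20, seed = 1)
  expect_equal(env1$envelope_sd, rep(0, 5))
})

test_that("the envelope equals an independent SD over the stored replicates", {
  members <- sprintf("m%02d", 1:20)
  tc <- program_timecourse(
    list(set = members),
    list(set = c(0.1, 0.5, 1.0, 0.4, 0.2)),
    n_extra = 50, noise_sd = 0.3, seed = 9
  )
  env <- remap_envelope(tc, members, fraction = 0.2, n_reps = 50, seed = 14)
  reps <- attr(env, "replicates")
  expect_equal(dim(reps), c(50, 5))
  expect_equal(env$envelope_sd, apply(reps, 2, sd))
  expect_true(any(env$envelope_sd > 0))

  # the permutation reading of remapping is available as a mode
  env_p <- remap_envelope(tc, members, fraction = 0.2, n_reps = 20, seed = 14,
                          mode = "permute")
  expect_equal(env_p$envelope_sd, apply(attr(env_p, "replicates"), 2, sd))
})

test_that("condition comparison pairs profiles and flags degenerate sets", {
  members <- sprintf("m%02d", 1:15)
  tc <- program_timecourse(
    list(set = members),
    list(set = c(0.1, 0.5, 1.0, 0.4, 0.2)),
    n_extra = 10, noise_sd = 0.1, seed = 3
  )
  same <- compare_conditions(tc, tc, list(reg = members))
  expect_equal(same$r, 1.0)
  expect_equal(same$flag, "ok")

  empty <- compare_conditions(tc, tc, list())
  expect_equal(nrow(empty), 0)

  bad <- tiny_timecourse(c(1, 2, 3), times = c(10, 20, 30))
  expect_error(compare_conditions(tc, bad, list(a = members)), "timepoints")
})

test_that("a planted regulatory shift lowers only the affected regulon's r", {
  affected <- sprintf("a%02d", 1:30)
  stable <- sprintf("s%02d", 1:30)
  prog_wt <- list(aff = c(0.1, 0.2, 0.6, 1.0, 0.3), sta = c(1.0, 0.8, 0.5, 0.2, 0.1))
  prog_mut <- list(aff = c(0.1, 0.2, 0.6, 0.95, 1.0), sta = prog_wt$sta)
  tc_wt <- program_timecourse(list(aff = affected, sta = stable), prog_wt,
                              noise_sd = 0.2, seed = 4)
  tc_mut <- program_timecourse(list(aff = affected, sta = stable), prog_mut,
                               noise_sd = 0.2, seed = 44)
  cmp <- compare_conditions(tc_wt, tc_mut, list(aff = affected, sta = stable))
  expect_lt(cmp$r[cmp$set_name == "aff"], cmp$r[cmp$set_name == "sta"])
})

test_that("time-courses round-trip through TSV and validate their schema", {
  tc <- program_timecourse(
    list(set = sprintf("m%02d", 1:5)),
    list(set = c(0.2, 0.6, 1.0, 0.5, 0.3)),
    n_extra = 3, noise_sd = 0.2, seed = 6
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_timecourse(tc, path)
  back <- read_timecourse(path)
  expect_equal(as.data.frame(back), as.data.frame(tc))
  expect_equal(timepoints(back), timepoints(tc))

  df <- data.frame(gene_id = c("a", "b"), `60` = c(1, NA), `120` = c(2, 3),
                   check.names = FALSE)
  expect_message(tc2 <- as_timecourse(df), "1 gene\\(s\\) dropped")
  expect_equal(tc2$gene_id, "a")
  expect_error(as_timecourse(data.frame(gene_id = "a", `60` = 1, check.names = FALSE)),
               "at least 2")
  expect_error(
    as_timecourse(data.frame(gene_id = "a", bad = 1, `60` = 2, check.names = FALSE)),
    "minutes"
  )
})

test_that("profile TSV output carries the envelope and a JSON sidecar", {
  members <- sprintf("m%02d", 1:10)
  tc <- program_timecourse(
    list(set = members), list(set = c(0.1, 0.5, 1.0, 0.4, 0.2)),
    n_extra = 20, noise_sd = 0.2, seed = 8
  )
  env <- remap_envelope(tc, members, fraction = 0.2, n_reps = 10, seed = 2,
                        set_name = "demo")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile(env, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(names(back), c("time", "value", "envelope_sd"))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$set_name, "demo")
  expect_equal(meta$n_reps, 10)
  expect_false(meta$degenerate)
})
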