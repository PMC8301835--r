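test_that("window grids tile, slide and wrap the circular chromosome", {
  tiles <- make_grid(10000, 1000, 1000)
  expect_equal(nrow(tiles), 10)
  expect_false(any(tiles$wraps))
  expect_equal(tiles$start, seq(0, 9000, by = 1000))

  sliding <- make_grid(10000, 1000, 500)
  expect_equal(nrow(sliding), 20)

  expect_error(make_grid(10000, 20000, 1000), "exceeds")
  expect_error(make_grid(10000, 1000, 2000), "step")
})

test_that("a wrap-around window contains TSSs on both sides of the origin", {
  ann <- genome_annotation(
    data.frame(gene_id = c("a", "b", "c"), tss = c(9900, 100, 5000), strand = "+"),
    10000
  )
  grid <- make_grid(10000, 1000, 500)
  w <- which(grid$start == 9500) # window [9500, 500)
  counts <- window_counts(ann, c("a", "b", "c"), grid)
  expect_equal(counts$observed[w], 2)
})

test_that("window counts conserve the set size on a tiling grid", {
  withr::with_seed(5, {
    ann <- random_annotation(200, 100000)
    tiles <- make_grid(100000, 10000, 10000)
    counts <- window_counts(ann, ann$gene_id, tiles)
    expect_equal(sum(counts$observed), 200)

    # single gene at tss 0 on 1 kb tiles
    one <- window_counts(ann, ann$gene_id[1], make_grid(100000, 1000, 1000))
    w0 <- 1 + ann$tss[1] %/% 1000
    expect_equal(one$observed[w0], 1)
    expect_equal(sum(one$observed), 1)

    # sliding grid counts each gene window_size/step times in total
    sliding <- make_grid(100000, 10000, 2000)
    gs <- sample(ann$gene_id, 37)
    cs <- window_counts(ann, gs, sliding)
    expect_equal(sum(cs$observed), 37 * (10000 / 2000))
  })
  expect_warning(
    window_counts(tiny_annotation(), character(0), make_grid(10000, 1000, 1000)),
    "empty gene set"
  )
  expect_error(
    window_counts(tiny_annotation(), "nope", make_grid(10000, 1000, 1000)),
    "absent from annotation"
  )
})

test_that("the full gene set as null (n = N) has zero SD everywhere", {
  ann <- tiny_annotation(20)
  grid <- make_grid(10000, 2500, 2500)
  expect_message(
    mom <- null_moments(ann, 20, grid, method = "analytic"),
    "null SD is 0"
  )
  k <- window_counts(ann, ann$gene_id, grid)$observed
  expect_equal(mom$null_mean, k)
  expect_equal(mom$null_sd, rep(0, 4))
})

test_that("Monte-Carlo null moments match the hypergeometric closed form", {
  ann <- random_annotation(30, 30000, seed = 8)
  grid <- make_grid(30000, 5000, 5000)
  exact <- null_moments(ann, 5, grid, method = "analytic")
  S <- 10000
  mc <- null_moments(ann, 5, grid, n_samples = S, seed = 21)
  se_mean <- exact$null_sd / sqrt(S)
  se_sd <- exact$null_sd / sqrt(2 * (S - 1))
  expect_true(all(abs(mc$null_mean - exact$null_mean) <= 3 * se_mean))
  expect_true(all(abs(mc$null_sd - exact$null_sd) <= 3 * se_sd))

  # two seeds agree within the reproducibility bound for a difference of means
  mc2 <- null_moments(ann, 5, grid, n_samples = S, seed = 22)
  expect_true(all(abs(mc$null_mean - mc2$null_mean) < 4 * sqrt(2) * se_mean))

  expect_warning(null_moments(ann, 5, grid, n_samples = 50, seed = 1), "noisy")
  expect_error(null_moments(ann, 0, grid), "set size")
})

test_that("Z-scores standardise counts and calls follow the |Z| > 2 rule", {
  ann <- tiny_annotation(20)
  grid <- make_grid(10000, 2500, 2500)
  mom <- null_moments(ann, 5, grid, method = "analytic")

  # observed == null mean everywhere -> all z = 0, all ns
  counts <- window_counts(ann, ann$gene_id[1:5], grid)
  counts$observed <- mom$null_mean
  zp <- z_from_counts(counts, mom)
  expect_equal(zp$z, rep(0, 4))
  expect_equal(zp$call, rep("ns", 4))

  # calls at the +-2 threshold
  counts$observed <- mom$null_mean + c(2.5, -2.5, 1.9, -1.9) * mom$null_sd
  zp <- z_from_counts(counts, mom)
  expect_equal(zp$call, c("enriched", "depleted", "ns", "ns"))

  # degenerate null -> undefined, never +-Inf
  mom0 <- mom
  mom0$null_sd <- rep(0, 4)
  zp0 <- z_from_counts(counts, mom0)
  expect_equal(zp0$call, rep("undefined", 4))
  expect_false(any(is.infinite(zp0$z)))
})

test_that("analytic Z-scores equal exhaustive enumeration over all subsets", {
  # N = 20 genes, 4 tiling windows, n = 4: enumerate all C(20,4) subsets
  ann <- random_annotation(20, 8000, seed = 13)
  grid <- make_grid(8000, 2000, 2000)
  M <- sapply(seq_len(4), function(w) {
    ((ann$tss - grid$start[w]) %% 8000) < 2000
  })
  subsets <- utils::combn(20, 4)
  counts_all <- apply(subsets, 2, function(idx) colSums(M[idx, , drop = FALSE]))
  enum_mean <- rowMeans(counts_all)
  enum_sd <- sqrt(rowMeans(counts_all^2) - enum_mean^2) # population SD
  exact <- null_moments(ann, 4, grid, method = "analytic")
  expect_equal(exact$null_mean, enum_mean, tolerance = 1e-10)
  expect_equal(exact$null_sd, enum_sd, tolerance = 1e-10)

  gs <- ann$gene_id[c(1, 5, 9, 13)]
  zp <- z_profile(ann, gs, grid, method = "analytic")
  obs <- colSums(M[c(1, 5, 9, 13), , drop = FALSE])
  expect_equal(zp$z, (obs - enum_mean) / enum_sd, tolerance = 1e-8)
})

test_that("spatial correlation behaves at its fixed points and edge cases", {
  ann <- random_annotation(100, 100000, seed = 4)
  grid <- make_grid(100000, 10000, 5000)
  zp <- z_profile(ann, ann$gene_id[1:20], grid, method = "analytic")
  expect_equal(spatial_correlation(zp, zp)$r, 1.0)

  neg <- zp
  neg$z <- -zp$z
  expect_equal(spatial_correlation(zp, neg)$r, -1.0)

  # fewer than 3 usable windows errors
  und <- zp
  und$call[-(1:2)] <- "undefined"
  expect_error(spatial_correlation(zp, und), "fewer than 3")

  flat <- zp
  flat$z <- rep(0.5, nrow(flat))
  expect_warning(res <- spatial_correlation(zp, flat), "zero variance")
  expect_true(is.na(res$r))
  expect_equal(res$flag, "zero_variance")
})

test_that("rotating coordinates and grid together leaves the profile unchanged", {
  ann <- random_annotation(150, 120000, seed = 17)
  delta <- 34567
  rotated <- genome_annotation(
    data.frame(
      gene_id = ann$gene_id,
      tss = (ann$tss + delta) %% 120000,
      strand = ann$strand
    ),
    120000
  )
  gs <- ann$gene_id[1:30]
  for (method in c("analytic", "montecarlo")) {
    zp1 <- z_profile(ann, gs, make_grid(120000, 20000, 5000),
                     method = method, n_samples = 500, seed = 3)
    zp2 <- z_profile(rotated, gs, make_grid(120000, 20000, 5000, offset = delta),
                     method = method, n_samples = 500, seed = 3)
    expect_equal(zp1$observed, zp2$observed)
    expect_equal(zp1$z, zp2$z)
    expect_equal(zp1$call, zp2$call)
  }
})

test_that("uniform gene sets produce calibrated Z-scores", {
  # reduced-size calibration check; the full-scale one runs in acceptance
  ann <- random_annotation(1000, 1e6, seed = 23)
  grid <- make_grid(1e6, 1e5, 2e4)
  zs <- withr::with_seed(31, {
    unlist(lapply(1:30, function(i) {
      gs <- sample(ann$gene_id, 100)
      z_profile(ann, gs, grid, method = "analytic")$z
    }))
  })
  expect_lt(abs(mean(zs)), 0.1)
  expect_gt(sd(zs), 0.8)
  expect_lt(sd(zs), 1.2)
})

test_that("a planted spatial cluster is recovered as enriched windows", {
  withr::with_seed(41, {
    len <- 1e6
    n_genes <- 1000
    # 80% of a 100-gene regulon inside [3e5, 4e5)
    cluster_tss <- sample(3e5:(4e5 - 1), 80)
    other_tss <- sample(setdiff(0:(len - 1), 3e5:(4e5 - 1)), n_genes - 80)
    ann <- genome_annotation(
      data.frame(
        gene_id = sprintf("g%04d", 1:n_genes),
        tss = c(cluster_tss, other_tss),
        strand = "+"
      ), len
    )
    regulon <- c(ann$gene_id[1:80], sample(ann$gene_id[81:n_genes], 20))
    grid <- make_grid(len, 5e4, 1e4)
    zp <- z_profile(ann, regulon, grid, n_samples = 2000, seed = 42)
    interior <- zp$start >= 3e5 & zp$end <= 4e5
    expect_gte(mean(zp$call[interior] == "enriched"), 0.8)
  })
})

test_that("Z-profile output writes joint TSV records and split BED lines", {
  ann <- random_annotation(50, 50000, seed = 2)
  grid <- make_grid(50000, 10000, 10000)
  zp <- z_profile(ann, ann$gene_id[1:10], grid, method = "analytic", set_name = "s")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_zprofile(zp, tsv, bed_path = bed)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(names(back), c("start", "end", "observed", "null_mean", "null_sd", "z", "call"))
  expect_equal(back$observed, zp$observed)
  bed_lines <- readr::read_tsv(bed, col_names = FALSE, show_col_types = FALSE)
  expect_equal(nrow(bed_lines), nrow(zp) + sum(zp$wraps))
})
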