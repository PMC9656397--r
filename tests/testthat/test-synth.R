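test_that("colony generator is a pure function of its seed", {
  ln <- default_lines()$IPS1
  ph <- default_phenotypes()$good
  a <- generate_colony_image(ln, ph, 24, seed = 11)
  b <- generate_colony_image(ln, ph, 24, seed = 11)
  expect_identical(a$cell_labels, b$cell_labels)
  expect_identical(a$footprint, b$footprint)
  c_ <- generate_colony_image(ln, ph, 24, seed = 12)
  expect_false(identical(a$cell_labels, c_$cell_labels))
})

test_that("generated images satisfy the container invariants", {
  img <- generate_colony_image(default_lines()$ES1, default_phenotypes()$bad,
                               48, seed = 3)
  labs <- sort(unique(img$cell_labels[img$cell_labels > 0]))
  expect_identical(labs, seq_len(max(labs)))       # contiguous labels
  expect_true(all(img$footprint[img$cell_labels > 0]))
  expect_gte(max(labs), 1)
})

test_that("zero gap fraction gives an exact tessellation with zero AIS", {
  img <- generate_colony_image(default_lines()$IPS1,
                               phenotype_spec("good", gap_fraction = 0),
                               24, seed = 5)
  expect_equal(colony_ais(img), 0)
})

test_that("realized gap fraction tracks the target across seeds", {
  ph <- phenotype_spec("good", gap_fraction = 0.15)
  ln <- default_lines()$IPS1
  g <- vapply(1:40, function(s) {
    img <- generate_colony_image(ln, ph, 24, seed = s)
    1 - sum(img$cell_labels > 0) / sum(img$footprint)
  }, numeric(1))
  expect_true(all(abs(g - 0.15) <= 0.03))
  expect_lt(abs(mean(g) - 0.15), 0.01)
})

test_that("generator rejects impossible targets", {
  expect_error(phenotype_spec("good", gap_fraction = 1),
               class = "colonymorph_domain")
  big <- line_spec("huge", area_24h = 1e7, growth_per_day = 1)
  expect_error(
    generate_colony_image(big, default_phenotypes()$good, 24, seed = 1),
    class = "colonymorph_sizing")
  expect_error(line_spec("shrink", growth_per_day = 0.5))
})

test_that("feature-table sample means obey the law of large numbers", {
  params <- descriptor_names("colony")
  mu <- c(area = 5e4, perimeter = 900, minor_axis = 210, feret_d = 290,
          min_feret_d = 230, shape_factor = 0.8, ais = 3000)
  gm <- data.frame(line = "L1", phenotype = "good", as.list(mu))
  sds <- abs(mu) * 0.1
  sigma <- diag(sds^2); dimnames(sigma) <- list(params, params)
  tab <- generate_feature_table(gm, sigma, n_per_group = 1e4, seed = 2)
  for (p in params) {
    expect_lt(abs(mean(tab[[p]]) - mu[[p]]), 3 * sds[[p]] / sqrt(1e4))
  }
  expect_true(all(tab$shape_factor <= 1 & tab$shape_factor > 0))
  expect_true(all(tab$phenotype == "good"))
})

test_that("feature-table generator enforces its preconditions", {
  params <- descriptor_names("colony")
  gm <- data.frame(line = "L1", phenotype = "good",
                   as.list(stats::setNames(rep(1, 7), params)))
  sigma <- diag(7); dimnames(sigma) <- list(params, params)
  expect_error(generate_feature_table(gm, sigma, n_per_group = 0, seed = 1),
               class = "colonymorph_domain")
  bad <- sigma; bad[1, 2] <- 0.5  # asymmetric
  expect_error(generate_feature_table(gm, bad, 10, seed = 1),
               class = "colonymorph_domain")
  npsd <- sigma; npsd[1, 2] <- npsd[2, 1] <- 2  # eigenvalue < 0
  expect_error(generate_feature_table(gm, npsd, 10, seed = 1),
               class = "colonymorph_domain")
})

test_that("a planted single-descriptor signal is separable by construction", {
  # delta = 2 sd => Bayes accuracy pnorm(1) ~ 0.84, well above majority 0.5
  recs <- planted_records(200, "ais", delta = 2, seed = 7)
  res <- train_cv(recs, "ais",
                  classifier_config("logistic", cv_repeats = 3L, seed = 1L))
  expect_gt(res$mean_accuracy, 0.5 + 3 * res$sem_accuracy)
  expect_gt(res$mean_accuracy, 0.7)
})

test_that("ct panels plant exact fold changes in the noise-free limit", {
  p0 <- generate_ct_panel(c("A", "B"), c("ref", "test"), fold_changes = 1,
                          noise_sd = 0, seed = 1)
  r0 <- relative_expression(p0, "group", reference_group = "ref")
  expect_true(all(r0$fold_change == 1))
  fc <- matrix(c(1, 1, 2, 1), 2, 2, dimnames = list(c("A", "B"), NULL))
  p2 <- generate_ct_panel(c("A", "B"), c("ref", "test"), fold_changes = fc,
                          noise_sd = 0, seed = 1)
  ct_a <- tapply(p2$ct[p2$gene == "A"], p2$group[p2$gene == "A"], mean)
  expect_equal(ct_a[["ref"]] - ct_a[["test"]], 1)  # one cycle lower = fold 2
  r2 <- relative_expression(p2, "group", reference_group = "ref")
  expect_equal(r2$fold_change[r2$gene == "A" & r2$group == "test"], 2)
  expect_equal(r2$fold_change[r2$gene == "B" & r2$group == "test"], 1)
  expect_error(generate_ct_panel("A", c("g1", "g2"), fold_changes = -1,
                                 noise_sd = 0, seed = 1),
               class = "colonymorph_domain")
})

test_that("noisy planted folds are recovered at high replication", {
  p <- generate_ct_panel("A", c("ref", "test"),
                         fold_changes = matrix(c(1, 0.5), 1, 2),
                         noise_sd = 0.2, n_bio = 50, seed = 9)
  r <- relative_expression(p, "group", reference_group = "ref")
  expect_lt(abs(r$fold_change[r$group == "test"] - 0.5), 0.05)
})

test_that("colony images survive a disk round-trip", {
  img <- generate_colony_image(default_lines()$IPS2,
                               default_phenotypes()$good, 24, seed = 4)
  prefix <- file.path(withr::local_tempdir(), "col")
  write_colony_image(img, prefix)
  back <- read_colony_image(prefix)
  expect_identical(back$cell_labels, img$cell_labels)
  expect_identical(back$footprint, img$footprint)
  expect_equal(back$pixel_size, img$pixel_size)
  expect_equal(back$meta$line, img$meta$line)
})
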