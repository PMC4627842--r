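test_that("simulation respects its configuration contract", {
  expect_error(simulation_config(seed = 1, prevalence = 0), "prevalence")
  expect_error(simulation_config(n_chains = 5), "seed")
  ds <- tiny_dataset()
  expect_length(ds$proteins, 10)
  for (id in names(ds$proteins)) {
    L <- nchar(ds$proteins[[id]]$sequence)
    expect_identical(nrow(ds$pssms[[id]]$scores), L)
    expect_identical(nrow(ds$structurals[[id]]$tab), L)
    expect_true(all(ds$pssms[[id]]$scores >= -13 &
                    ds$pssms[[id]]$scores <= 13))
  }
})

test_that("same seed reproduces the dataset exactly; seeds differ otherwise", {
  cfg <- simulation_config(n_chains = 4, length_mean = 60, length_sd = 10,
                           seed = 7)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$proteins, d2$proteins)
  expect_identical(d1$pssms, d2$pssms)
  expect_identical(d1$structurals, d2$structurals)
  d3 <- simulate_dataset(simulation_config(n_chains = 4, length_mean = 60,
                                           length_sd = 10, seed = 8))
  expect_false(identical(d1$proteins, d3$proteins))
})

test_that("realized disorder prevalence is near the target at scale", {
  ds <- simulate_dataset(simulation_config(n_chains = 100,
                                           length_mean = 150,
                                           length_sd = 40, seed = 12))
  labs <- unlist(lapply(ds$proteins, `[[`, "labels"))
  expect_lt(abs(mean(labs == "D") - 0.24), 0.05)
  expect_lt(abs(mean(labs == "U") - 0.05), 0.02)
})

test_that("disordered segments carry the advertised feature shifts", {
  ds <- simulate_dataset(simulation_config(n_chains = 30, length_mean = 200,
                                           length_sd = 30, seed = 33,
                                           unknown_rate = 0))
  coil_d <- c(); coil_o <- c(); asa_d <- c(); asa_o <- c()
  aa_d <- c(); aa_o <- c()
  for (id in names(ds$proteins)) {
    lab <- ds$proteins[[id]]$labels
    tab <- ds$structurals[[id]]$tab
    coil_d <- c(coil_d, tab$p_coil[lab == "D"])
    coil_o <- c(coil_o, tab$p_coil[lab == "O"])
    asa_d <- c(asa_d, tab$asa[lab == "D"])
    asa_o <- c(asa_o, tab$asa[lab == "O"])
    ch <- strsplit(ds$proteins[[id]]$sequence, "")[[1]]
    aa_d <- c(aa_d, ch[lab == "D"]); aa_o <- c(aa_o, ch[lab == "O"])
  }
  expect_gt(mean(coil_d) - mean(coil_o), 0.3)
  expect_gt(mean(asa_d) - mean(asa_o), 0.2)
  # disorder-prone composition enrichment
  prone <- c("D", "G", "S", "E", "K", "P")
  expect_gt(mean(aa_d %in% prone), mean(aa_o %in% prone) + 0.1)
})

test_that("at signal zero the two states are statistically identical", {
  ds <- simulate_dataset(simulation_config(n_chains = 20, length_mean = 150,
                                           length_sd = 20, signal = 0,
                                           seed = 44, unknown_rate = 0))
  coil_d <- c(); coil_o <- c()
  for (id in names(ds$proteins)) {
    lab <- ds$proteins[[id]]$labels
    tab <- ds$structurals[[id]]$tab
    coil_d <- c(coil_d, tab$p_coil[lab == "D"])
    coil_o <- c(coil_o, tab$p_coil[lab == "O"])
  }
  expect_lt(abs(mean(coil_d) - mean(coil_o)), 0.02)
})

test_that("fixture bundles round-trip and regenerate byte-identically", {
  cfg <- simulation_config(n_chains = 3, length_mean = 50, length_sd = 5,
                           seed = 5)
  ds <- simulate_dataset(cfg)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_fixture_bundle(ds, dir1)
  write_fixture_bundle(simulate_dataset(cfg), dir2)
  files <- sort(list.files(dir1))
  # 1 FASTA + 3 per-chain files for each chain
  expect_length(files, 1 + 3 * 3)
  for (f in files)
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  back <- read_fixture_bundle(dir1)
  expect_identical(names(back$proteins), names(ds$proteins))
  for (id in names(ds$proteins)) {
    expect_identical(back$proteins[[id]]$sequence,
                     ds$proteins[[id]]$sequence)
    expect_identical(back$proteins[[id]]$labels, ds$proteins[[id]]$labels)
    expect_equal(unname(back$pssms[[id]]$scores),
                 unname(ds$pssms[[id]]$scores))
    expect_equal(back$structurals[[id]]$tab$p_coil,
                 ds$structurals[[id]]$tab$p_coil, tolerance = 1e-4)
  }
})

test_that("cross-validated AUC is monotone in signal strength", {
  aucs <- vapply(c(0, 0.5, 1), function(s) {
    ds <- simulate_dataset(simulation_config(n_chains = 10,
                                             length_mean = 80,
                                             length_sd = 10, signal = s,
                                             seed = 202))
    feat <- featurize_dataset(ds$proteins, ds$pssms, ds$structurals,
                              window = 3)
    cv <- cross_validate(feat$x, feat$meta, hyper_params(window = 3L),
                         k = 3, split = "sequence", seed = 15, n_boot = 0,
                         calib_max = 1500)
    cv$pooled$AUC
  }, 0)
  expect_true(all(diff(aucs) >= 0))
  expect_lt(aucs[1], 0.65)
  expect_gt(aucs[3], 0.9)
})
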