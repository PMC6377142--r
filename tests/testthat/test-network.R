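sim_links <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- small_sim(seed = 1)
      cfg <- dyde_config(rng_seed = 1)
      cache <<- list(
        sim = sim,
        A = fit_all_pairs(sim$baseline, cfg = cfg),
        B = fit_all_pairs(sim$perturbed, cfg = cfg))
    }
    cache
  }
})

test_that("fit_all_pairs fits n^2 - n models deterministically", {
  sl <- sim_links()
  expect_equal(nrow(sl$A), 6 * 5)          # 6 genes
  expect_false(any(sl$A$source == sl$A$target))

  # 2 genes -> 2 models
  two <- fit_all_pairs(sl$sim$baseline, c("D1", "G2"),
                       dyde_config(rng_seed = 1))
  expect_equal(nrow(two), 2)
  # the same pair fitted within a different gene subset is identical
  expect_equal(two[two$target == "G2", c("a", "b", "c", "fitness_pct")],
               sl$A[sl$A$source == "D1" & sl$A$target == "G2",
                    c("a", "b", "c", "fitness_pct")],
               tolerance = 1e-12, ignore_attr = TRUE)

  # true links outscore non-links on average
  truth_key <- paste(sl$sim$truth$source, sl$sim$truth$target)
  is_true <- paste(sl$A$source, sl$A$target) %in% truth_key
  expect_gt(mean(sl$A$fitness_pct[is_true]),
            mean(sl$A$fitness_pct[!is_true]))
})

test_that("validate_links thresholds monotonically and annotates sign", {
  sl <- sim_links()
  net46 <- validate_links(sl$A, 46)
  expect_true(all(net46$links$fitness_pct >= 46))
  expect_true(all(net46$links$sign %in% c("activates", "inhibits")))
  expect_equal(nrow(validate_links(sl$A, 100 + 1e-6)$links), 0)
  sizes <- vapply(seq(0, 100, by = 10),
                  function(t) nrow(validate_links(sl$A, t)$links), 1L)
  expect_true(all(diff(sizes) <= 0))
  # every lower-threshold network contains the higher-threshold one
  k80 <- with(validate_links(sl$A, 80)$links, paste(source, target))
  k46 <- with(net46$links, paste(source, target))
  expect_true(all(k80 %in% k46))
})

test_that("compare_networks partitions links and scores common ones", {
  sl <- sim_links()
  netA <- validate_links(sl$A, 80)
  netB <- validate_links(sl$B, 80)
  cmp <- compare_networks(netA, netB)
  expect_equal(nrow(cmp$common) + nrow(cmp$lost), nrow(netA$links))
  expect_true(all(cmp$common$nugap >= 0 & cmp$common$nugap <= 1))

  # identical networks: no lost/gained, all nu-gaps zero
  cmp0 <- compare_networks(netA, netA)
  expect_equal(nrow(cmp0$lost), 0)
  expect_equal(nrow(cmp0$gained), 0)
  expect_true(all(cmp0$common$nugap < 1e-9))

  # connectivity bookkeeping: in + out degree, loss percentage in range
  con <- cmp$connectivity
  expect_true(all(con$loss_pct >= 0 & con$loss_pct <= 100))
  g <- con$gene[1]
  expect_equal(con$connectivity_A[1],
               sum(netA$links$source == g | netA$links$target == g))
})

test_that("rank_nu_gaps orders by gap then lexicographically", {
  sl <- sim_links()
  cmp <- compare_networks(validate_links(sl$A, 80), validate_links(sl$B, 80))
  top <- rank_nu_gaps(cmp, 3)
  expect_true(all(diff(top$nugap) <= 0))
  expect_lte(nrow(top), 3)
  # k beyond the number of common links returns everything
  expect_equal(nrow(rank_nu_gaps(cmp, 1000)), nrow(cmp$common))
  # ties (identical networks -> all zero) break lexicographically
  cmp0 <- compare_networks(validate_links(sl$A, 80), validate_links(sl$A, 80))
  all0 <- rank_nu_gaps(cmp0, 1000)
  expect_equal(order(all0$source, all0$target), seq_len(nrow(all0)))
  expect_error(rank_nu_gaps(cmp, 0), "k")
})

test_that("threshold_sweep against the shipped synthetic reference", {
  sl <- sim_links()
  ref <- read.table(system.file("extdata", "synthetic_reference_network.tsv",
                                package = "dyde"),
                    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  expect_equal(ref, sl$sim$truth[, c("source", "target")],
               ignore_attr = TRUE)
  sw <- threshold_sweep(sl$A, ref, c(0, 46, 80, 90, 101))
  # monotone non-increasing coverage and false positives
  expect_true(all(diff(sw$true_positives) <= 0))
  expect_true(all(diff(sw$false_positives) <= 0))
  expect_equal(sw$coverage_pct, 100 * sw$true_positives / nrow(ref))
  # threshold 0 keeps every fitted pair: FP maximal
  expect_equal(sw$false_positives[1], nrow(sl$A) - nrow(ref))
  expect_equal(sw$true_positives[1], nrow(ref))
  # above 100 nothing validates
  expect_equal(sw$n_validated[5], 0)
  # brute-force recount at one threshold
  v <- sl$A[sl$A$fitness_pct >= 80, ]
  tp <- sum(paste(v$source, v$target) %in% paste(ref$source, ref$target))
  expect_equal(sw$true_positives[3], tp)
  expect_equal(sw$false_positives[3], nrow(v) - tp)
  expect_error(threshold_sweep(sl$A, ref[0, ], 46), "reference")
})

test_that("connectivity_loss_sensitivity matches direct recomputation", {
  sl <- sim_links()
  sens <- connectivity_loss_sensitivity(sl$A, sl$B, 80, delta_pct = 5)
  # identical link sets -> zero sd and zero mean
  self <- connectivity_loss_sensitivity(sl$A, sl$A, 80)
  expect_true(all(self$loss_sd_pct == 0))
  expect_true(all(self$loss_mean_pct == 0))
  # brute-force oracle over the three thresholds
  genes <- sort(unique(c(sl$A$source, sl$A$target)))
  loss_at <- function(t) {
    va <- sl$A[sl$A$fitness_pct >= t, ]
    vb <- sl$B[sl$B$fitness_pct >= t, ]
    kb <- paste(vb$source, vb$target)
    vapply(genes, function(g) {
      tou <- va$source == g | va$target == g
      if (!sum(tou)) return(0)
      100 * sum(tou & !(paste(va$source, va$target) %in% kb)) / sum(tou)
    }, 1)
  }
  L <- cbind(loss_at(75), loss_at(80), loss_at(85))
  expect_equal(sens$loss_mean_pct, unname(apply(L, 1, mean)),
               tolerance = 1e-12)
  expect_equal(sens$loss_sd_pct, unname(apply(L, 1, sd)), tolerance = 1e-12)
  expect_error(connectivity_loss_sensitivity(sl$A, sl$B, 4, 5), "delta")
})

test_that("genome_scan_perturbed finds the single perturbed link", {
  sl <- sim_links()
  cfg <- dyde_config(rng_seed = 1)
  scan <- genome_scan_perturbed(sl$sim$baseline, sl$sim$perturbed,
                                sl$sim$baseline$gene_ids, cfg)
  expect_equal(nrow(scan$candidates), 1)
  expect_equal(scan$candidates$source, "D1")
  expect_equal(scan$candidates$target, "G2")
  expect_true(all(scan$high_fitness$fitness_pct >= 80 &
                  scan$high_fitness$fitness_pct_B >= 80))
  # identical conditions -> no candidates
  scan0 <- genome_scan_perturbed(sl$sim$baseline, sl$sim$baseline,
                                 sl$sim$baseline$gene_ids, cfg)
  expect_equal(nrow(scan0$candidates), 0)
  expect_true(all(scan0$high_fitness$nugap < 1e-9))
})

test_that("genome_scan_hubs ranks a hub wired to core genes", {
  # hub regulated by one driver, plus two unrelated noise genes; core set =
  # the D2 cascade.  The hub's links survive in both conditions (the
  # perturbation does not touch D2's module), the noise genes' do not.
  spec <- synthetic_spec(
    genes = c("D2", "G3", "G4", "HUB"),
    adjacency = data.frame(source = c("D2", "D2", "D2"),
                           target = c("G3", "G4", "HUB"),
                           a = c(0.6, 0.3, 0.5), b = c(0.5, 0.35, 0.45),
                           c = c(2, 2.5, 2), stringsAsFactors = FALSE),
    drivers = list(D2 = list(A = 1.2, phi1 = 0, p1 = 29, p2 = 23,
                             baseline = 7.5)),
    perturbed_link = list(source = "D2", target = "G4",
                          a = 0.12, b = 0.9, c = 2.5),
    seed = 5)
  sim <- simulate_pair(spec)
  set.seed(5)
  noise <- expression_dataset(
    array(8 + rnorm(2 * 2 * 12, 0, 0.7), c(2, 2, 12)),
    c("N1", "N2"), sim$baseline$times, "baseline")
  bind_ds <- function(ds, extra) {
    n1 <- dim(ds$values)[1]; n2 <- dim(extra$values)[1]
    arr <- array(NA_real_, c(n1 + n2, dim(ds$values)[2], dim(ds$values)[3]))
    arr[seq_len(n1), , ] <- ds$values
    arr[n1 + seq_len(n2), , ] <- extra$values
    expression_dataset(arr, c(ds$gene_ids, extra$gene_ids), ds$times,
                       ds$condition)
  }
  dsA <- bind_ds(sim$baseline, noise)
  dsB <- bind_ds(sim$perturbed, noise)
  cfg <- dyde_config(rng_seed = 5)
  scan <- genome_scan_hubs(dsA, dsB, core_genes = c("D2", "G3", "G4"),
                           candidate_genes = c("HUB", "N1", "N2"), cfg = cfg)
  expect_gt(nrow(scan$ranking), 0)
  expect_equal(scan$ranking$gene[1], "HUB")
  expect_true(all(scan$links$fitness_A >= 60 & scan$links$fitness_B >= 60))
  expect_true(all(scan$links$nugap <= cfg$nugap_threshold))
  # empty result when nothing clears the bar
  cfg100 <- dyde_config(hub_fit_threshold_pct = 100, rng_seed = 5)
  expect_equal(nrow(genome_scan_hubs(dsA, dsB, c("D2", "G3", "G4"),
                                     c("N1", "N2"), cfg100)$ranking), 0)
})

test_that("network JSON and SIF exports round-trip", {
  sl <- sim_links()
  net <- validate_links(sl$A, 80)
  jp <- tempfile(fileext = ".json")
  write_network_json(net, jp)
  back <- read_network_json(jp)
  expect_equal(back$links$fitness_pct, net$links$fitness_pct)
  expect_equal(back$threshold_pct, 80)
  sp <- tempfile(fileext = ".sif")
  write_network_sif(net, sp)
  sif <- read.table(sp, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(nrow(sif), nrow(net$links))
  expect_true(all(sif$V2 %in% c("activates", "inhibits")))
})
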