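test_that("truth generation follows the configured distribution and transition matrix", {
  ident <- diag(3); dimnames(ident) <- list(c("ACTIVE", "PAUSED", "SILENT"),
                                            c("ACTIVE", "PAUSED", "SILENT"))
  p <- sim_params(n_genes = 500, transition_matrix = ident, seed = 3)
  tr <- generate_truth(p)
  expect_equal(tr$state_2, tr$state_1)

  p_all_active <- sim_params(n_genes = 100, state_dist = c(1, 0, 0),
                             transition_matrix = ident, seed = 3)
  expect_true(all(generate_truth(p_all_active)$state_1 == "ACTIVE"))

  # default changing fraction stays inside a 3-sigma binomial band of the
  # configured 12% at n = 2000
  band <- 3 * sqrt(0.12 * 0.88 / 2000)
  for (s in 1:5) {
    tr <- generate_truth(sim_params(n_genes = 2000, seed = s))
    expect_lt(abs(mean(tr$state_1 != tr$state_2) - 0.12), band)
  }
  expect_error(sim_params(state_dist = c(0.9, 0.2, 0.1)), "summing to 1")
})

test_that("the default transition matrix encodes the configured category shares", {
  m <- default_transition_matrix()
  expect_equal(unname(rowSums(m)), rep(1, 3))
  d <- c(0.47, 0.48, 0.05)
  flows <- d * m  # absolute masses
  changing <- sum(flows) - sum(diag(flows))
  expect_equal(changing, 0.12)
  expect_equal((flows["PAUSED", "ACTIVE"] + flows["SILENT", "ACTIVE"]) /
                 changing, 0.22)
  expect_equal(flows["SILENT", "PAUSED"] / changing, 0.30, ignore_attr = TRUE)
  expect_equal(flows["PAUSED", "SILENT"] / changing, 0.31, ignore_attr = TRUE)
  expect_equal((flows["SILENT", "ACTIVE"] + flows["ACTIVE", "SILENT"]) /
                 changing, 0.01)
})

test_that("noise-free ChIP simulation is decoded exactly by the metagene caller", {
  p <- sim_params(n_genes = 150, chip_noise_sd = 0, seed = 5)
  truth <- generate_truth(p)
  chip <- simulate_chip(truth, p, condition = 1)
  expect_equal(nrow(chip), 150 * 33)
  calls <- call_chip(chip)
  expect_equal(setNames(calls$bound, calls$gene_id)[truth$gene_id],
               setNames(truth$state_1 %in% c("ACTIVE", "PAUSED"),
                        truth$gene_id))
  # the TSS probe of an initiating locus carries exactly the peak height
  g <- truth$gene_id[truth$state_1 == "PAUSED"][1]
  prof <- build_metagene(chip[chip$gene_id == g, ])
  expect_equal(prof$log_ratio[prof$offset == 0], 2.0)
})

test_that("binding calls err on fewer than 1% of loci at the default noise level", {
  p <- sim_params(n_genes = 2000, seed = 6)
  truth <- generate_truth(p)
  calls <- call_chip(simulate_chip(truth, p, condition = 1))
  truth_bound <- truth$state_1 %in% c("ACTIVE", "PAUSED")
  err <- mean(calls$bound[match(truth$gene_id, calls$gene_id)] != truth_bound)
  expect_lt(err, 0.01)
})

test_that("expression simulation gives near-perfect transcript calls at the default shift", {
  p <- sim_params(n_genes = 1500, seed = 8)
  truth <- generate_truth(p)
  expr <- rbind(simulate_expression(truth, p, 1, 1),
                simulate_expression(truth, p, 1, 2))
  det <- detect_expression(expr)
  calls <- call_transcripts(det, filter_probes(det))
  acc <- mean(calls$expressed[match(truth$gene_id, calls$gene_id)] ==
                (truth$state_1 == "ACTIVE"))
  expect_gte(acc, 0.99)
})

test_that("a zero intensity shift reduces expressed calls to the false-positive rate", {
  p <- sim_params(n_genes = 1000, expr_shift_sds = 0, seed = 9)
  truth <- generate_truth(p)
  expr <- simulate_expression(truth, p, 1, 1)
  det <- detect_expression(expr)
  calls <- call_transcripts(det)  # no filtering: raw alpha-level behaviour
  expect_lt(mean(calls$expressed), 0.01)
})

test_that("synthetic studies are byte-identical across runs under one seed", {
  p <- sim_params(n_genes = 60, seed = 10)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  simulate_study(p, d1)
  simulate_study(p, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  d3 <- file.path(tempdir(), "det3")
  simulate_study(sim_params(n_genes = 60, seed = 11), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "truth.tsv"))),
                         unname(tools::md5sum(file.path(d3, "truth.tsv")))))
})

test_that("generated study files are consumable by every pipeline reader", {
  p <- sim_params(n_genes = 80, seed = 12)
  st <- simulate_study(p)
  ann <- read_tss_annotation(st$tss)
  expect_equal(nrow(ann), 80)
  chip <- read_probe_signals(st$chip[[1]], ann)
  expect_equal(nrow(chip), 80 * 33)
  expect_equal(attr(chip, "n_dropped"), 0L)
  expr <- read_expression_table(st$expr)
  expect_equal(length(unique(expr$sample_id)), 4L)
  ont <- read_gene2go(st$gene2go)
  expect_true(all(grepl("^GO:[0-9]{7}$", ont$terms$go_id)))
})

test_that("lineage terms draw at least 80% of members from their archetype pool", {
  # pools only exceed the per-term pure draw at study scale
  p <- sim_params(n_genes = 2000, seed = 14)
  truth <- generate_truth(p)
  g2g <- generate_go_annotations(truth, p)
  lin <- attr(g2g, "term_lineage")
  for (id in names(lin)[lin != "background"]) {
    members <- g2g$gene_id[g2g$go_id == id]
    frac <- mean(truth$lineage[match(members, truth$gene_id)] == lin[[id]])
    expect_gte(frac, 0.8 * 0.9)  # purity less the random-fill overlap slack
  }
})

test_that("the full pipeline recovers the truth exactly on noise-free data", {
  p <- sim_params(n_genes = 300, chip_noise_sd = 0, expr_noise = 0,
                  seed = 13)
  st <- simulate_study(p)
  res <- run_transition_analysis(st$tss, st$chip, st$expr)
  truth <- st$truth
  s1 <- res$states$before
  s2 <- res$states$after
  expect_equal(nrow(s1), 300)
  expect_equal(setNames(s1$state, s1$gene_id)[truth$gene_id],
               setNames(truth$state_1, truth$gene_id))
  expect_equal(setNames(s2$state, s2$gene_id)[truth$gene_id],
               setNames(truth$state_2, truth$gene_id))
  # tally equals the generator's realised transition matrix exactly
  truth_counts <- table(factor(truth$state_1, levels = c("ACTIVE", "PAUSED",
                                                         "SILENT")),
                        factor(truth$state_2, levels = c("ACTIVE", "PAUSED",
                                                         "SILENT")))
  expect_equal(as.vector(res$tally$counts), as.vector(truth_counts))
  expect_equal(res$tally$n_discordant, 0L)
})
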