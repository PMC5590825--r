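test_that("simulation configs are validated", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(concentration_cs = 0))
  expect_error(simulation_config(frac_low_coverage = 1.5))
  expect_error(simulation_config(shift_size = 0.6))  # could push mu below 0
  expect_error(simulation_config(ratio_mean_range = c(0.2, 0.9)))
})

test_that("generated tables are schema-complete with exact isoform sums", {
  cfg <- simulation_config(n_genes = 50, seed = 11)
  sim <- simulate_expression(cfg)
  tab <- sim$table
  # every (gene, isoform, accession) combination present
  expect_equal(nrow(tab), 50L * 2L * 16L)
  expect_true(all(tab$fpkm >= 0))
  # the two isoform FPKMs reconstruct the drawn ratio exactly
  iso1 <- tab[grepl("\\.1$", tab$isoform_id), ]
  iso2 <- tab[grepl("\\.2$", tab$isoform_id), ]
  tot <- iso1$fpkm + iso2$fpkm
  r_back <- iso1$fpkm / tot
  r_truth <- sim$truth$ratio[cbind(iso1$gene_id, iso1$accession_id)]
  expect_equal(r_back, unname(r_truth), tolerance = 1e-12)
})

test_that("generation is byte-identical at a fixed seed and varies across seeds", {
  cfg <- simulation_config(n_genes = 30, seed = 9)
  s1 <- simulate_expression(cfg)
  s2 <- simulate_expression(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_expression(simulation_config(n_genes = 30, seed = 10))
  expect_false(identical(s1$table$fpkm, s3$table$fpkm))
  expect_identical(names(s1$table), names(s3$table))
  # protein generator is deterministic too
  expect_identical(simulate_protein_pairs(3, seed = 4),
                   simulate_protein_pairs(3, seed = 4))
})

test_that("per-gene ratio means converge to the planted compartment means", {
  cfg <- simulation_config(n_genes = 400, n_cs = 10, n_ws = 10, seed = 21,
                           frac_median_shift = 0.1)
  sim <- simulate_expression(cfg)
  tr <- sim$truth
  for (comp in c("cs", "ws")) {
    accs <- if (comp == "cs") sim$cs_panel$accessions else sim$ws_panel$accessions
    mu <- tr$genes[[paste0("mu_", comp)]]
    emp <- rowMeans(tr$ratio[, accs, drop = FALSE])
    # Beta sd / sqrt(n accessions), a 3-sigma band per gene
    kap <- if (comp == "cs") cfg$concentration_cs else cfg$concentration_ws
    sem <- sqrt(mu * (1 - mu) / (kap + 1) / length(accs))
    expect_gt(mean(abs(emp - mu) < 3 * sem), 0.95)
  }
})

test_that("equal concentrations give indistinguishable dispersion, unequal do not", {
  # null regime: same concentration, equal panel sizes
  cfg0 <- simulation_config(n_genes = 2000, n_cs = 8, n_ws = 8,
                            concentration_cs = 60, concentration_ws = 60,
                            frac_median_shift = 0, frac_low_coverage = 0,
                            seed = 31)
  sim0 <- simulate_expression(cfg0)
  v_cs <- apply(sim0$truth$ratio[, sim0$cs_panel$accessions], 1, var)
  v_ws <- apply(sim0$truth$ratio[, sim0$ws_panel$accessions], 1, var)
  expect_gt(suppressWarnings(ks.test(v_cs, v_ws)$p.value), 0.01)

  # contrast regime: Beta variance mu(1-mu)/(kappa+1) decreases in kappa
  cfg1 <- simulation_config(n_genes = 2000, seed = 32)
  sim1 <- simulate_expression(cfg1)
  v_cs <- apply(sim1$truth$ratio[, sim1$cs_panel$accessions], 1, var)
  v_ws <- apply(sim1$truth$ratio[, sim1$ws_panel$accessions], 1, var)
  expect_gt(median(v_ws), median(v_cs))
})

test_that("planted GO annotation concentrates the enriched term in shifted genes", {
  cfg <- simulation_config(n_genes = 1000, frac_median_shift = 0.05, seed = 41)
  sim <- simulate_expression(cfg)
  gm <- simulate_go(cfg, sim$truth)
  shifted <- sim$truth$genes$gene_id[sim$truth$genes$shifted]
  others <- setdiff(sim$truth$genes$gene_id, shifted)
  has_term <- function(g) {
    !is.null(gm$go[[g]]) && gm$enriched_term %in% gm$go[[g]]
  }
  f_in <- mean(vapply(shifted, has_term, logical(1)))
  f_out <- mean(vapply(others, has_term, logical(1)))
  expect_gt(f_in, 0.3)   # p_in = 0.5
  expect_lt(f_out, 0.1)  # p_out = 0.04
  # no shifted genes: the term reduces to background
  cfg0 <- simulation_config(n_genes = 500, frac_median_shift = 0, seed = 42)
  sim0 <- simulate_expression(cfg0)
  gm0 <- simulate_go(cfg0, sim0$truth)
  f0 <- mean(vapply(sim0$truth$genes$gene_id, function(g)
    !is.null(gm0$go[[g]]) && gm0$enriched_term %in% gm0$go[[g]], logical(1)))
  expect_lt(f0, 0.1)
})

test_that("protein pairs realise their planted construction rules", {
  pp <- simulate_protein_pairs(8, seed = 13)
  tr <- pp$truth
  # category 4: translation recovers a protein identical to the canonical
  for (g in tr$gene_id[tr$category == 4L]) {
    res <- translate_alternative(isoform_pair(
      g, pp$canonical_protein[[g]], pp$canonical_cds_prefix[[g]],
      alternative_mrna = pp$alternative_mrna[[g]]))
    expect_identical(res$protein, pp$canonical_protein[[g]])
  }
  # category 2: predicted protein shorter than 20% of canonical
  for (g in tr$gene_id[tr$category == 2L]) {
    res <- translate_alternative(isoform_pair(
      g, pp$canonical_protein[[g]], pp$canonical_cds_prefix[[g]],
      alternative_mrna = pp$alternative_mrna[[g]]))
    expect_lt(nchar(res$protein), 0.2 * nchar(pp$canonical_protein[[g]]))
  }
  # category 1: the canonical start context is absent
  for (g in tr$gene_id[tr$category == 1L]) {
    res <- translate_alternative(isoform_pair(
      g, pp$canonical_protein[[g]], pp$canonical_cds_prefix[[g]],
      alternative_mrna = pp$alternative_mrna[[g]]))
    expect_identical(res$status, "start_not_found")
  }
})
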