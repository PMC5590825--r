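# wrap a plain ratio matrix as the container compare_panels expects
ratio_matrix <- function(values, cs_acc, ws_acc) {
  structure(list(values = values, genes = rownames(values),
                 accessions = colnames(values),
                 numerator_isoform = setNames(paste0(rownames(values), ".t1"),
                                              rownames(values)),
                 cs_accessions = cs_acc, ws_accessions = ws_acc,
                 rejected_zero_total = character(0)),
            class = "et_ratio_matrix")
}

test_that("spread summaries match hand-computed values", {
  vals <- rbind(g1 = c(0.5, 0.5, 0.5, 0.5, 0.5),
                g2 = c(0.5, 0.6, 0.7, 0.8, 0.9))
  colnames(vals) <- paste0("a", 1:5)
  m <- ratio_matrix(vals, paste0("a", 1:5), character(0))
  s <- gene_spread(m, panel_definition("p", "CS", paste0("a", 1:5)))
  expect_equal(s$sigma_r, c(0, 0.025))
  expect_equal(s$iq_r, c(0, 0.2))     # Q1 = 0.6, Q3 = 0.8 at rank 1+(n-1)p
  expect_equal(s$med_r, c(0.5, 0.7))
  expect_equal(s$avg_r, c(0.5, 0.7))

  vals2 <- rbind(g1 = c(0, 1))
  colnames(vals2) <- c("a1", "a2")
  m2 <- ratio_matrix(vals2, c("a1", "a2"), character(0))
  s2 <- gene_spread(m2, panel_definition("p", "CS", c("a1", "a2")))
  expect_equal(s2$sigma_r, 0.5)  # n-1 denominator
  expect_equal(s2$iq_r, 0.5)

  # quartiles agree with the reference linear-interpolation convention
  withr::local_seed(3)
  vals3 <- matrix(runif(60), 10, 6,
                  dimnames = list(paste0("g", 1:10), paste0("a", 1:6)))
  m3 <- ratio_matrix(vals3, paste0("a", 1:6), character(0))
  s3 <- gene_spread(m3, panel_definition("p", "CS", paste0("a", 1:6)))
  expect_equal(s3$iq_r, unname(apply(vals3, 1, function(x)
    unname(diff(quantile(x, c(0.25, 0.75), type = 7))))))

  expect_error(gene_spread(m2, panel_definition("p", "CS", "a1")),
               "fewer than 2")
})

test_that("panel comparison handles identical columns and exact fits", {
  withr::local_seed(5)
  cs_acc <- paste0("c", 1:4); ws_acc <- paste0("w", 1:4)
  base <- matrix(runif(40, 0.5, 1), 10, 4)
  vals <- cbind(base, base)
  dimnames(vals) <- list(paste0("g", 1:10), c(cs_acc, ws_acc))
  m <- ratio_matrix(vals, cs_acc, ws_acc)
  cs <- panel_definition("cs", "CS", cs_acc)
  ws <- panel_definition("ws", "WS", ws_acc)
  expect_warning(cmp <- compare_panels(m, cs, ws, "sigma_r"),
                 "all spread differences are zero")
  expect_equal(cmp$n_cs_eq_ws, 10L)
  expect_equal(cmp$mean_diff, 0)
  expect_equal(cmp$p_wilcoxon, 1)

  # exact linear relation WS = 0.5 * CS in spread => slope exactly 0.5
  s <- seq(0.01, 0.1, length.out = 8)
  vals2 <- rbind(do.call(rbind, lapply(s, function(si)
    c(0.7 + si * c(-1, 1, -1, 1), 0.7 + 0.5 * si * c(-1, 1, -1, 1)))))
  dimnames(vals2) <- list(paste0("g", 1:8), c(cs_acc, ws_acc))
  m2 <- ratio_matrix(vals2, cs_acc, ws_acc)
  cmp2 <- compare_panels(m2, cs, ws, "iq_r")
  expect_equal(cmp2$slope, 0.5, tolerance = 1e-10)
  expect_equal(cmp2$n_cs_gt_ws, 8L)
})

test_that("comparisons are invariant to gene order", {
  withr::local_seed(6)
  cs_acc <- paste0("c", 1:6); ws_acc <- paste0("w", 1:6)
  vals <- matrix(rbeta(50 * 12, 5, 2), 50, 12,
                 dimnames = list(paste0("g", 1:50), c(cs_acc, ws_acc)))
  m <- ratio_matrix(vals, cs_acc, ws_acc)
  perm <- sample(50)
  mp <- ratio_matrix(vals[perm, ], cs_acc, ws_acc)
  cs <- panel_definition("cs", "CS", cs_acc)
  ws <- panel_definition("ws", "WS", ws_acc)
  for (st in c("sigma_r", "iq_r")) {
    a <- compare_panels(m, cs, ws, st)
    b <- compare_panels(mp, cs, ws, st)
    for (f in c("n_cs_gt_ws", "n_cs_eq_ws", "n_cs_lt_ws", "slope",
                "mean_diff", "p_paired_t", "p_wilcoxon")) {
      expect_equal(a[[f]], b[[f]], tolerance = 1e-12)
    }
  }
})

test_that("panel subsampling is reproducible, distinct, and bounded", {
  panel <- panel_definition("popCS_10", "CS", paste0("CS", 1:10))
  subs <- subsample_panel(panel, 6, 4, seed = 99)
  expect_length(subs, 4L)
  expect_equal(vapply(subs, function(p) p$label, character(1)),
               paste0("popCS_6_", 1:4))
  keys <- vapply(subs, function(p) paste(sort(p$accessions), collapse = ","),
                 character(1))
  expect_equal(anyDuplicated(keys), 0L)
  expect_identical(subs, subsample_panel(panel, 6, 4, seed = 99))

  # whole panel: only one subset of size 10 exists
  whole <- subsample_panel(panel, 10, 1, seed = 1)
  expect_equal(sort(whole[[1]]$accessions), sort(panel$accessions))
  expect_error(subsample_panel(panel, 10, 2, seed = 1), "only 1")
  expect_error(subsample_panel(panel, 6, 300, seed = 1), "only 210")
  expect_error(subsample_panel(panel, 11, 1, seed = 1), "exceeds")
})

test_that("the comparison battery reruns filters per panel pair", {
  sim <- simulate_expression(simulation_config(n_genes = 300, seed = 17))
  cs_subs <- subsample_panel(sim$cs_panel, 6, 3, seed = 1)
  res <- run_all_comparisons(sim$table, c(list(sim$cs_panel), cs_subs),
                             sim$ws_panel)
  expect_length(res, 8L)  # 4 panels x 2 statistics
  counts <- vapply(res, function(x) x$n_genes, numeric(1))
  # gene sets legitimately differ between panel pairs
  expect_gt(length(unique(counts)), 1L)
  out <- withr::local_tempfile()
  write_comparisons(res, out)
  expect_equal(length(readLines(out)), 9L)
})
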