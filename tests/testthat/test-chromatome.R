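toy_table <- function() {
  # 2 proteins, 2 replicates each, hand-computable means
  chromatome_table(data.frame(
    protein_id = rep(c("A", "B"), each = 8),
    condition = rep(rep(c("minusEdU", "Luc", "2Cneg", "2Cpos"), each = 2), 2),
    replicate = rep(1:2, 8),
    psm = c(
      2, 2, 8, 8, 4, 4, 2, 2, # A: control 2, Luc 8, 2Cneg 4, 2Cpos 2
      5, 5, 5, 5, 5, 5, 5, 5 # B: flat
    )
  ))
}

test_that("log2 fold change to control follows the pseudocount formula", {
  tbl <- toy_table()
  fc <- log2fc_to_control(tbl, "Luc")
  expect_equal(fc$log2fc[fc$protein_id == "A"], log2(9 / 3)) # ~1.585
  expect_equal(fc$log2fc[fc$protein_id == "B"], 0)
  expect_error(log2fc_to_control(tbl[tbl$condition != "minusEdU", ], "Luc"), "minusEdU")

  # spiked 4x protein recovered within +-0.3 of log2FC 2 at 5 replicates
  spec <- chromatome_sim_spec(
    n_proteins = 200L,
    replicates = c(minusEdU = 5L, Luc = 5L, `2Cneg` = 5L, `2Cpos` = 5L),
    baseline_mean = 20, minus_edu_mean = 20,
    spike_sets = list(sp = list(
      proteins = sprintf("P%04d", 1:30),
      folds = c(Luc = 4, `2Cneg` = 1, `2Cpos` = 1)
    ))
  )
  sim <- simulate_chromatome(spec, seed = 61)
  fc2 <- log2fc_to_control(sim$table, "Luc")
  est <- mean(fc2$log2fc[1:30])
  expect_lt(abs(est - 2), 0.3)
})

test_that("pairwise enrichment is reciprocal and matches direct computation", {
  tbl <- toy_table()
  ab <- pairwise_enrichment(tbl, "Luc", "2Cneg")
  ba <- pairwise_enrichment(tbl, "2Cneg", "Luc")
  expect_equal(ab$fold * ba$fold, rep(1, 2))
  expect_equal(ab$fold[ab$protein_id == "A"], 9 / 5)
  expect_equal(ab$fold[ab$protein_id == "B"], 1)
})

test_that("average enrichment: geometric and arithmetic modes", {
  # protein with pairwise folds {2, 8}: geometric mean 4, arithmetic 5
  tbl <- chromatome_table(data.frame(
    protein_id = "A",
    condition = c("minusEdU", "Luc", "2Cneg", "2Cpos"),
    replicate = 1L,
    psm = c(0, 15, 7, 1) # folds (15+1)/(7+1)=2 and (15+1)/(1+1)=8
  ))
  geo <- average_enrichment(tbl, "Luc", c("2Cneg", "2Cpos"), mode = "geometric")
  expect_equal(geo$avg_fold, 4)
  ari <- average_enrichment(tbl, "Luc", c("2Cneg", "2Cpos"), mode = "arithmetic")
  expect_equal(ari$avg_fold, 5)
  # single comparison condition reduces to the pairwise fold
  single <- average_enrichment(tbl, "Luc", "2Cpos")
  expect_equal(single$avg_fold, 8)
})

test_that("venn decomposition matches brute-force enumeration", {
  # all 8 selection patterns represented
  flags <- expand.grid(
    selected_Luc = c(FALSE, TRUE),
    selected_2Cneg = c(FALSE, TRUE),
    selected_2Cpos = c(FALSE, TRUE)
  )
  flags <- flags[rep(seq_len(8), times = c(3, 1, 2, 5, 1, 4, 2, 7)), ]
  venn <- select_and_venn(flags)
  # brute force: count each pattern
  oracle <- table(apply(flags, 1, function(r) {
    m <- c("Luc", "2Cneg", "2Cpos")[as.logical(r)]
    if (length(m) == 0) "none" else paste(m, collapse = "&")
  }))
  for (lab in names(oracle)) {
    expect_equal(venn$n[venn$venn_region == lab], as.integer(oracle[[lab]]))
  }
  expect_equal(sum(venn$n), nrow(flags))
  # permutation invariance
  withr::local_seed(13)
  perm <- flags[sample(nrow(flags)), ]
  expect_equal(select_and_venn(perm), venn)
})

test_that("selection flag is exactly avg_fold >= cutoff", {
  sim <- simulate_chromatome(spiked_chromatome_spec(), seed = 3)
  enr <- chromatome_enrichment(sim$table)
  expect_identical(enr$selected_Luc, enr$avg_fold_Luc >= 2)
  expect_identical(enr$selected_2Cpos, enr$avg_fold_2Cpos >= 2)
  # venn label consistent with flags
  row <- enr[enr$selected_Luc & enr$selected_2Cneg & !enr$selected_2Cpos, ]
  if (nrow(row) > 0) expect_true(all(row$venn_region == "Luc&2Cneg"))
})

test_that("protein ranking is deterministic with lexicographic ties", {
  enr <- tibble::tibble(
    protein_id = c("pZ", "pA", "pM", "pB"),
    log2fc_Luc = c(2, 3, 2, 1)
  )
  rk <- rank_proteins(enr, "Luc", top_n = 4)
  expect_equal(rk$protein_id, c("pA", "pM", "pZ", "pB"))
  # reversed input order gives identical ranking; top_1 is the argmax
  rk2 <- rank_proteins(enr[4:1, ], "Luc", top_n = 4)
  expect_equal(rk2, rk)
  expect_equal(rank_proteins(enr, "Luc", top_n = 1)$protein_id, "pA")
  expect_warning(big <- rank_proteins(enr, "Luc", top_n = 10), "returning all")
  expect_equal(nrow(big), 4L)

  # random tables match a plain sort oracle
  withr::local_seed(71)
  r <- tibble::tibble(
    protein_id = sprintf("Q%03d", sample(999, 50)),
    log2fc_Luc = round(rnorm(50), 1)
  )
  rk3 <- rank_proteins(r, "Luc", top_n = 50)
  oracle <- r[order(-r$log2fc_Luc, r$protein_id), ]
  expect_equal(rk3$protein_id, oracle$protein_id)
})

test_that("replicate QC computes Pearson matrices and flags low-yield runs", {
  tbl <- toy_table()
  qc <- replicate_qc(tbl)
  cm <- qc$cor_matrix
  expect_true(isSymmetric(cm))
  expect_equal(unname(diag(cm)), rep(1, nrow(cm)))
  # identical replicates correlate at exactly 1
  expect_equal(cm["Luc_r1", "Luc_r2"], 1)

  # closed-form Pearson on a 4-protein toy table
  t4 <- chromatome_table(data.frame(
    protein_id = rep(c("A", "B", "C", "D"), 2),
    condition = "Luc",
    replicate = rep(1:2, each = 4),
    psm = c(1, 2, 3, 4, 2, 3, 5, 6)
  ))
  qc4 <- replicate_qc(t4)
  x <- c(1, 2, 3, 4)
  y <- c(2, 3, 5, 6)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(qc4$cor_matrix["Luc_r1", "Luc_r2"], r_hand)

  # a replicate with abnormally low total PSM is flagged
  low <- simulate_chromatome(chromatome_sim_spec(n_proteins = 100L), seed = 5)$table
  low$psm[low$condition == "2Cpos" & low$replicate == 2L] <-
    round(low$psm[low$condition == "2Cpos" & low$replicate == 2L] * 0.1)
  qc_low <- replicate_qc(low)
  expect_true(any(qc_low$flagged$condition == "2Cpos" & qc_low$flagged$replicate == 2L))

  # zero-variance replicate reported missing with reason
  zv <- chromatome_table(data.frame(
    protein_id = rep(c("A", "B"), 2), condition = "Luc",
    replicate = rep(1:2, each = 2), psm = c(3, 3, 1, 2)
  ))
  qczv <- replicate_qc(zv)
  expect_true(is.na(qczv$cor_matrix["Luc_r1", "Luc_r2"]))
  expect_match(qczv$correlations$note[1], "zero-variance")
})

test_that("tidy and glance methods return well-formed tibbles", {
  sim <- simulate_chromatome(spiked_chromatome_spec(), seed = 9)
  enr <- chromatome_enrichment(sim$table)
  long <- generics::tidy(enr)
  expect_equal(nrow(long), nrow(enr) * 3L)
  expect_true(all(c("condition", "log2fc", "avg_fold", "selected") %in% names(long)))
  gl <- generics::glance(enr)
  expect_equal(gl$n_proteins, 500L)
  expect_gte(gl$n_luc_2cneg_not_2cpos, 30L)
})
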