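make_filter_fixture <- function() {
  # 10 probes x 2 conditions x 2 replicates (treated + control);
  # hand-set IQRs via condition means, presence patterns and annotation
  samples <- toy_samples(n_cond = 4L, reps = 2L)
  probes <- sprintf("p%02d", 1:10)
  cond_means <- rbind(
    p01 = c(0, 10, 20, 30),   # high IQR
    p02 = c(5, 5, 5, 5),      # constant -> IQR 0
    p03 = c(0, 1, 2, 3),      # modest IQR
    p04 = c(0, 20, 40, 60),   # highest IQR
    p05 = c(2, 2, 2, 2.1),    # near-constant
    p06 = c(0, 8, 16, 24),
    p07 = c(1, 1.2, 1.4, 1.6),
    p08 = c(0, 12, 24, 36),
    p09 = c(0, 9, 18, 27),    # unannotated
    p10 = c(0, 15, 30, 45))   # absent calls
  tcols <- samples$sample_id[samples$group == "treated"]
  ccols <- samples$sample_id[samples$group == "control"]
  intensity <- matrix(0, 10, length(c(tcols, ccols)),
                      dimnames = list(probes, c(tcols, ccols)))
  for (j in seq_len(4L)) {
    cols <- samples$sample_id[samples$condition_id == sprintf("cond_%02d", j)]
    intensity[, cols] <- cond_means[, j]
  }
  presence <- matrix(1L, 10, ncol(intensity), dimnames = dimnames(intensity))
  presence["p10", tcols] <- 0L  # never fully present
  probe2gene <- setNames(sub("p", "g", probes), probes)
  probe2gene <- probe2gene[names(probe2gene) != "p09"]
  list(intensity = intensity, presence = presence, samples = samples,
       probe2gene = probe2gene)
}

test_that("probe filter applies the three rules like a manual pass", {
  fx <- make_filter_fixture()
  out <- filter_probes(fx$intensity, fx$presence, fx$samples, fx$probe2gene,
                       iqr_quantile = 0.5, present_frac = 0.25)
  # manual application: drop p09 (no annotation); IQRs of the remaining 9
  # probes, median threshold; then p10 fails present calls
  cm <- sapply(sprintf("cond_%02d", 1:4), function(cc)
    rowMeans(fx$intensity[names(fx$probe2gene),
                          fx$samples$sample_id[fx$samples$condition_id == cc]]))
  iqrs <- apply(cm, 1, function(x) diff(quantile(x, c(.25, .75))))
  thr <- unname(quantile(iqrs, 0.5))
  manual <- names(iqrs)[iqrs >= thr]
  manual <- setdiff(manual, "p10")
  expect_setequal(rownames(out$intensity), manual)
  expect_equal(out$report$n_no_annotation, 1L)
  expect_equal(out$report$n_absent, 1L)
  expect_false("p02" %in% rownames(out$intensity))  # constant probe removed
})

test_that("probe filter is idempotent", {
  fx <- make_filter_fixture()
  once <- filter_probes(fx$intensity, fx$presence, fx$samples, fx$probe2gene)
  twice <- filter_probes(once$intensity, once$presence, fx$samples,
                         once$probe2gene)
  expect_identical(rownames(twice$intensity), rownames(once$intensity))
  expect_equal(unclass(twice$intensity), unclass(once$intensity),
               ignore_attr = TRUE)
})

test_that("all probes removed raises an explicit error", {
  fx <- make_filter_fixture()
  empty_map <- fx$probe2gene[0]
  expect_error(filter_probes(fx$intensity, fx$presence, fx$samples,
                             empty_map), "all probes removed")
})

test_that("condition log-ratios are mean treated minus mean control", {
  samples <- toy_samples(n_cond = 1L, reps = 2L)
  intensity <- matrix(c(4, 6, 3, 5), 1,
                      dimnames = list("g1", samples$sample_id))
  lr <- condition_log_ratios(intensity, samples)
  expect_equal(unname(lr[1, 1]), 1.0)

  # treated == control values -> zero column
  intensity2 <- matrix(c(3, 5, 3, 5), 1,
                       dimnames = list("g1", samples$sample_id))
  expect_equal(unname(condition_log_ratios(intensity2, samples)[1, 1]), 0)
})

test_that("log-ratios with uneven replicate counts match direct means", {
  # 3 conditions with 3, 2 and 1 treated replicates
  samples <- do.call(rbind, lapply(1:3, function(j) {
    reps <- c(3L, 2L, 1L)[j]
    rbind(data.frame(sample_id = sprintf("c%d_t%d", j, seq_len(reps)),
                     condition_id = sprintf("cond_%02d", j),
                     chemical = "x", dose = 1, duration = 1,
                     group = "treated",
                     control_condition_id = sprintf("ctrl_%02d", j),
                     histopath_score = 0L, stringsAsFactors = FALSE),
          data.frame(sample_id = sprintf("c%d_r%d", j, 1:2),
                     condition_id = sprintf("ctrl_%02d", j),
                     chemical = "vehicle", dose = 0, duration = 1,
                     group = "control",
                     control_condition_id = NA_character_,
                     histopath_score = NA_integer_,
                     stringsAsFactors = FALSE))
  }))
  set.seed(11)
  intensity <- matrix(rnorm(5 * nrow(samples)), 5,
                      dimnames = list(sprintf("g%d", 1:5),
                                      samples$sample_id))
  lr <- condition_log_ratios(intensity, samples)
  for (j in 1:3) {
    tcols <- samples$sample_id[samples$condition_id == sprintf("cond_%02d", j)]
    ccols <- samples$sample_id[samples$condition_id == sprintf("ctrl_%02d", j)]
    manual <- rowMeans(intensity[, tcols, drop = FALSE]) -
      rowMeans(intensity[, ccols, drop = FALSE])
    expect_equal(lr[, sprintf("cond_%02d", j)], manual)
  }
})

test_that("log-ratio computation is linear in treated intensities", {
  st <- generate_study(small_cfg(seed = 4L))
  lr0 <- condition_log_ratios(st$intensity, st$samples)
  cc <- colnames(lr0)[3]
  shifted <- st$intensity
  tcols <- st$samples$sample_id[st$samples$condition_id == cc]
  shifted[, tcols] <- shifted[, tcols] + 2.5
  lr1 <- condition_log_ratios(shifted, st$samples)
  expect_equal(lr1[, cc], lr0[, cc] + 2.5)
  expect_equal(lr1[, colnames(lr1) != cc], lr0[, colnames(lr0) != cc])
})

test_that("missing control mapping errors with the condition name", {
  samples <- toy_samples(n_cond = 1L, reps = 2L)
  samples$control_condition_id[samples$group == "treated"] <- "ctrl_99"
  intensity <- matrix(1, 1, 4, dimnames = list("g1", samples$sample_id))
  expect_error(condition_log_ratios(intensity, samples), "cond_01")
})

test_that("probe collapsing keeps the most variable probe per gene", {
  m <- rbind(pA = c(1, 2, 3, 4),
             pB = c(10, 10, 10, 10),
             pC = c(5, 6, 7, 8))
  colnames(m) <- sprintf("c%03d", 1:4)
  # pA and pB -> gene1 (pA has IQR 1.5, pB 0); pC -> gene2
  p2g <- c(pA = "gene1", pB = "gene1", pC = "gene2")
  out <- collapse_probes(m, p2g)
  expect_setequal(rownames(out), c("gene1", "gene2"))
  expect_equal(out["gene1", ], m["pA", ])
  expect_equal(attr(out, "kept_probes")[["gene1"]], "pA")

  # tie in IQR -> lexicographically smaller probe id wins
  m2 <- rbind(pZ = c(1, 2, 3, 4), pY = c(1, 2, 3, 4))
  colnames(m2) <- colnames(m)
  out2 <- collapse_probes(m2, c(pZ = "gene1", pY = "gene1"))
  expect_equal(attr(out2, "kept_probes")[["gene1"]], "pY")

  # one probe per gene: pure relabeling
  out3 <- collapse_probes(m, c(pA = "g1", pB = "g2", pC = "g3"))
  expect_equal(unname(out3["g2", ]), unname(m["pB", ]))
})

test_that("disease-condition selection is strict on the severity score", {
  samples <- toy_samples(
    n_cond = 7L, reps = 2L, scores = c(2L, 2L, 2L, 2L, 1L, 0L, 1L),
    chemicals = c("1-Naphthylisothiocyanate", "1-Naphthylisothiocyanate",
                  "4,4'-Methylenedianiline", "N-Nitrosodimethylamine",
                  "mild_a", "none_b", "mild_c"),
    dose = c(30, 60, 81, 10, 5, 5, 5),
    duration = c(7, 7, 5, 5, 5, 5, 5))
  sel <- select_disease_conditions(samples, score_threshold = 1L)
  expect_identical(sel, sprintf("cond_%02d", 1:4))

  expect_warning(none <- select_disease_conditions(samples, 2L),
                 "no condition")
  expect_length(none, 0L)

  sel0 <- select_disease_conditions(samples, score_threshold = 0L)
  expect_setequal(sel0, sprintf("cond_%02d", c(1:5, 7)))
})

test_that("replicate-clustering QC flags conditions that sit with controls", {
  set.seed(21)
  samples <- toy_samples(n_cond = 3L, reps = 3L, scores = rep(2L, 3))
  n_genes <- 200L
  base <- rnorm(n_genes, 8)
  intensity <- sapply(seq_len(nrow(samples)), function(i) {
    x <- base + rnorm(n_genes, sd = 0.2)
    if (samples$group[i] == "treated" &&
        samples$condition_id[i] != "cond_02") {
      x[1:40] <- x[1:40] + 2  # clear treatment response
    }
    x  # cond_02 treated replicates look exactly like controls
  })
  dimnames(intensity) <- list(sprintf("g%03d", seq_len(n_genes)),
                              samples$sample_id)
  qc <- qc_replicate_clustering(intensity, samples,
                                sprintf("cond_%02d", 1:3))
  expect_false(qc$pass[qc$condition_id == "cond_02"])
  expect_true(all(qc$pass[qc$condition_id != "cond_02"]))

  expect_error(qc_replicate_clustering(intensity, samples, "cond_01"),
               "at least 2")
})

test_that("a null condition among shifted ones is flagged across seeds", {
  flagged <- vapply(1:15, function(s) {
    set.seed(s)
    samples <- toy_samples(n_cond = 3L, reps = 3L)
    n_genes <- 150L
    base <- rnorm(n_genes, 8)
    intensity <- sapply(seq_len(nrow(samples)), function(i) {
      x <- base + rnorm(n_genes, sd = 0.4)
      if (samples$group[i] == "treated" &&
          samples$condition_id[i] != "cond_03") {
        x[1:30] <- x[1:30] + 1.5
      }
      x
    })
    dimnames(intensity) <- list(sprintf("g%03d", seq_len(n_genes)),
                                samples$sample_id)
    qc <- qc_replicate_clustering(intensity, samples,
                                  sprintf("cond_%02d", 1:3))
    !qc$pass[qc$condition_id == "cond_03"]
  }, logical(1L))
  expect_gte(mean(flagged), 0.95)
})
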