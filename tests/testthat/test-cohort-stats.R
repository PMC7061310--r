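test_that("differential testing matches exact rank-sum enumeration", {
  # small two-group comparison with no ties: enumerate all group splits
  xa <- c(1.3, 2.1, 0.7, 3.5)
  xb <- c(4.2, 5.1, 3.9, 6.0)
  mat <- matrix(c(xa, xb), ncol = 1, dimnames = list(paste0("s", 1:8), "f"))
  d <- differential(mat, rep(c("a", "b"), each = 4), "a", "b")

  pooled <- c(xa, xb)
  r <- rank(pooled)
  w_obs <- sum(r[5:8]) - 4 * 5 / 2           # Mann-Whitney U of group b
  combs <- utils::combn(8, 4)
  u_null <- apply(combs, 2, function(ix) sum(r[ix]) - 10)
  p_exact <- mean(abs(u_null - 8) >= abs(w_obs - 8))
  expect_equal(d$p, p_exact, tolerance = 1e-12)
  expect_equal(d$log2fc, log2(median(xb) / median(xa)))
})

test_that("differential handles degenerate and swapped groups", {
  set.seed(42)
  a <- matrix(rnorm(100 * 3, 10), ncol = 3,
              dimnames = list(paste0("h", 1:100), c("f1", "f2", "const")))
  b <- a
  b[, "f1"] <- b[, "f1"] + 5          # large shift
  rownames(b) <- paste0("t", 1:100)
  b[, "const"] <- 1; a2 <- a; a2[, "const"] <- 1
  mat <- rbind(a2, b)
  grp <- rep(c("h", "t"), each = 100)
  d <- differential(mat, grp, "h", "t")
  expect_lt(d$q[d$feature == "f1"], 0.05)
  expect_gt(d$log2fc[d$feature == "f1"], 0)
  expect_true(d$degenerate[d$feature == "const"])
  expect_equal(d$p[d$feature == "const"], 1)

  dsw <- differential(mat, grp, "t", "h")
  expect_equal(dsw$log2fc, -d$log2fc)
  expect_equal(dsw$p, d$p)
})

test_that("BH correction equals the brute-force definition", {
  # printed example
  mat <- NULL
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(stats::p.adjust(p, "BH"), rep(0.04, 4))
  expect_equal(bh_oracle(p), rep(0.04, 4))
  set.seed(11)
  for (i in 1:5) {
    pv <- stats::runif(50)^2
    expect_equal(stats::p.adjust(pv, "BH"), bh_oracle(pv), tolerance = 1e-12)
  }
})

test_that("methylation windows are strand-aware and average beta values", {
  genes <- data.frame(
    gene_id = c("gp", "gm"), chrom = "chr1",
    start = c(5000L, 5000L), end = c(5080L, 5080L),
    strand = c("+", "-"), amino_acid = "Pro",
    anticodon = c("AGG", "TGG"), is_mito = FALSE,
    genomic_seq = strrep("A", 80), stringsAsFactors = FALSE)
  genes$introns <- replicate(2, matrix(integer(0), ncol = 2L),
                             simplify = FALSE)
  betas <- data.frame(
    chrom = "chr1",
    pos = c(4000L, 5040L, 5060L, 6000L),
    s1 = c(0.8, 0.2, 0.4, 0.6))
  res <- promoter_methylation(genes[1, ], betas, mode = "array")
  # plus strand: window [TSS-1500, gene end] = [3501, 5080]
  expect_equal(unname(res$gene["gp", "s1"]), mean(c(0.8, 0.2, 0.4)))
  res_m <- promoter_methylation(genes[2, ], betas, mode = "array")
  # minus strand: upstream is to the right -> [5001, 6580]
  expect_equal(unname(res_m$gene["gm", "s1"]), mean(c(0.2, 0.4, 0.6)))
  # bisulfite mode restricts to the gene body
  res_b <- promoter_methylation(genes[1, ], betas, mode = "bisulfite")
  expect_equal(unname(res_b$gene["gp", "s1"]), mean(c(0.2, 0.4)))
  # no probes in window -> missing, coverage reflects it
  far <- data.frame(chrom = "chr1", pos = 99000L, s1 = 0.5)
  res_0 <- promoter_methylation(genes, far, mode = "array")
  expect_true(all(is.na(res_0$gene)))
  expect_equal(res_0$coverage, 0)
})

test_that("isoacceptor methylation averages member genes", {
  genes <- data.frame(
    gene_id = c("g1", "g2"), chrom = "chr1",
    start = c(1000L, 9000L), end = c(1080L, 9080L),
    strand = "+", amino_acid = "Pro", anticodon = "AGG", is_mito = FALSE,
    genomic_seq = strrep("A", 80), stringsAsFactors = FALSE)
  genes$introns <- replicate(2, matrix(integer(0), ncol = 2L),
                             simplify = FALSE)
  betas <- data.frame(chrom = "chr1", pos = c(1050L, 9050L),
                      s1 = c(0.2, 0.6))
  res <- promoter_methylation(genes, betas, mode = "bisulfite")
  expect_equal(unname(res$isoacceptor["AGG", "s1"]), 0.4)
})

test_that("copy number projects segments with overlap weighting", {
  genes <- data.frame(
    gene_id = c("inside", "spanning", "outside"), chrom = "chr1",
    start = c(100L, 970L, 5000L), end = c(180L, 1070L, 5080L),
    strand = "+", amino_acid = "Pro",
    anticodon = c("AGG", "AGG", "CGG"), is_mito = FALSE,
    genomic_seq = strrep("A", 80), stringsAsFactors = FALSE)
  genes$introns <- replicate(3, matrix(integer(0), ncol = 2L),
                             simplify = FALSE)
  segments <- data.frame(
    chrom = "chr1", start = c(1L, 1001L), end = c(1000L, 2000L),
    s1 = c(0, 1))
  res <- gene_cna(genes, segments)
  expect_equal(unname(res$gene["inside", "s1"]), 0)
  # 30 bases in segment 0 (971..1000), 70 in segment 1 (1001..1070)
  expect_equal(unname(res$gene["spanning", "s1"]), 0.7)
  expect_true(is.na(res$gene["outside", "s1"]))
  expect_equal(unname(res$isoacceptor["AGG", "s1"]), mean(c(0, 0.7)))
})

test_that("MLR recovers noiseless coefficients exactly and flags bad fits", {
  set.seed(9)
  n <- 40L
  me <- runif(n); cna <- rnorm(n)
  d <- data.frame(isoacceptor = "AGG", condition = "c1",
                  sample = paste0("s", 1:n),
                  abundance = 2 - 3 * me + 1.5 * cna, me = me, cna = cna)
  fit <- suppressWarnings(fit_isoacceptor_mlr(d))  # perfect-fit lm warning
  expect_equal(fit$b0, 2, tolerance = 1e-9)
  expect_equal(fit$bMe, -3, tolerance = 1e-9)
  expect_equal(fit$bCNA, 1.5, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)

  d2 <- d; d2$me <- 0.5
  fit2 <- fit_isoacceptor_mlr(d2)
  expect_false(fit2$fitted)
  expect_equal(fit2$skip_reason, "rank_deficient")

  d3 <- d[1:3, ]
  fit3 <- fit_isoacceptor_mlr(d3)
  expect_equal(fit3$skip_reason, "insufficient_samples")
})

test_that("coefficient sign test matches the exact binomial sums", {
  mk <- function(n_pos, n_neg) {
    data.frame(isoacceptor = paste0("a", seq_len(n_pos + n_neg)),
               condition = "c1",
               bMe = c(rep(1, n_pos), rep(-1, n_neg)),
               q_me = 0.01, stringsAsFactors = FALSE)
  }
  expect_equal(coefficient_sign_test(mk(8, 2), "me")$p, 0.109375)
  expect_equal(coefficient_sign_test(mk(5, 5), "me")$p, 1)
  expect_equal(coefficient_sign_test(mk(10, 0), "me")$p, 2 * 0.5^10,
               tolerance = 1e-12)
  none <- mk(1, 1); none$q_me <- 0.9
  res <- coefficient_sign_test(none, "me")
  expect_true(is.na(res$p))
  expect_equal(res$flag, "no_significant_coefficients")
})

test_that("Kaplan-Meier estimates equal the product-limit oracle", {
  # all-event single group: survival after deaths at 1,2,3 is 2/3, 1/3, 0
  clin <- data.frame(patient = paste0("p", 1:3), time = c(1, 2, 3),
                     event = 1L)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = clin)
  expect_equal(summary(fit)$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km_oracle(clin$time, clin$event)$surv, c(2 / 3, 1 / 3, 0))

  # random censoring pattern against the direct formula
  set.seed(77)
  time <- round(rexp(40, 0.1), 1)
  event <- rbinom(40, 1, 0.7)
  fit2 <- survival::survfit(
    survival::Surv(time, event) ~ 1,
    data = data.frame(time = time, event = event))
  orc <- km_oracle(time, event)
  sm <- summary(fit2, times = orc$time)
  expect_equal(sm$surv, orc$surv, tolerance = 1e-12)
})

test_that("SDAw stratification builds 40% groups and tests survival", {
  # identical survival in both tails -> log-rank p = 1
  sdaw <- setNames(1:10, paste0("p", 1:10))
  clin <- data.frame(patient = paste0("p", 1:10),
                     time = c(5, 6, 7, 8, 1, 1, 5, 6, 7, 8),
                     event = rep(1L, 10))
  sv <- survival_by_sdaw(sdaw, clin, fraction = 0.4)
  expect_equal(sv$n_low, 4L)
  expect_equal(sv$n_high, 4L)
  expect_setequal(sv$groups$patient[sv$groups$group == "low"],
                  paste0("p", 1:4))
  expect_equal(sv$logrank_p, 1, tolerance = 1e-9)

  # group with no events keeps survival at 1
  clin2 <- clin; clin2$event[clin2$patient %in% paste0("p", 7:10)] <- 0L
  sv2 <- survival_by_sdaw(sdaw, clin2, fraction = 0.4)
  sm <- summary(sv2$fit)
  high_surv <- sm$surv[as.character(sm$strata) == "group=high"]
  expect_true(all(high_surv == 1) || length(high_surv) == 0L)

  # separated hazards are detected
  co <- simulate_cohort(sim_config(seed = 15L))
  sv3 <- survival_by_sdaw(setNames(co$survival$sdaw, co$survival$patient),
                          co$survival)
  expect_lt(sv3$logrank_p, 0.01)
})

test_that("a threefold hazard ratio is detected in nearly every replicate", {
  hits <- vapply(1:40, function(r) {
    co <- simulate_cohort(sim_config(seed = 900L + r))
    sv <- survival_by_sdaw(setNames(co$survival$sdaw, co$survival$patient),
                           co$survival)
    sv$logrank_p < 0.01
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("survival codon scan restricts candidates by the up-down margin", {
  set.seed(30)
  feats <- c("CCA", "CCG", "GGT")
  diff_list <- lapply(1:8, function(i) {
    data.frame(feature = feats,
               log2fc = c(1, -0.2, 0.3),
               q = c(0.01, 0.5, ifelse(i <= 4, 0.01, 0.5)),
               stringsAsFactors = FALSE)
  })
  # CCA: up in 8, down in 0 -> margin 8 > 5; GGT: up in 4 -> margin 4
  cand <- select_survival_codons(diff_list, min_margin = 5L)
  expect_equal(cand, "CCA")

  co <- simulate_cohort(sim_config(seed = 16L))
  m <- cbind(CCA = co$survival$sdaw,
             GGT = rev(co$survival$sdaw))
  rownames(m) <- co$survival$patient
  scan <- survival_codon_scan(m, co$survival, c("CCA", "GGT"))
  expect_equal(nrow(scan), 2L)
  expect_equal(scan$q, stats::p.adjust(scan$logrank_p, "BH"))
})
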