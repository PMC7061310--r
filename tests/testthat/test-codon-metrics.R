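# Independent oracle for the wobble decoding weights, formulated per codon
# (recognizing anticodons and their pairing penalty index) rather than per
# codon box: the Watson-Crick decoder is the codon's reverse complement,
# and the wobble decoder depends on the third codon base -- U3 is also read
# by G34 (penalty s5), C3 by inosine/A34 (s6), A3 by inosine/A34 (s7), and
# G3 by U34 (s8). ATG is read by CAT alone.
tai_w_oracle <- function(t, s) {
  t_of <- function(ac) if (ac %in% names(t)) unname(t[ac]) else 0
  stops <- c("TAA", "TAG", "TGA")
  for (ac in rc_oracle(stops)) t[ac] <- 0
  W <- c()
  for (cod in codonSDA::sense_codons()) {
    wc <- rc_oracle(cod)
    third <- substr(cod, 3L, 3L)
    wc_pen <- switch(third, T = s[1], C = s[2], A = s[3], G = s[4])
    if (cod == "ATG") {
      W[cod] <- (1 - s[4]) * t_of("CAT")
      next
    }
    wob <- switch(third,
      T = rc_oracle(paste0(substr(cod, 1, 2), "C")),  # G34 reads U3
      C = rc_oracle(paste0(substr(cod, 1, 2), "T")),  # A34 (inosine) reads C3
      A = rc_oracle(paste0(substr(cod, 1, 2), "T")),  # A34 (inosine) reads A3
      G = rc_oracle(paste0(substr(cod, 1, 2), "A")))  # U34 reads G3
    wob_pen <- switch(third, T = s[5], C = s[6], A = s[7], G = s[8])
    W[cod] <- (1 - wc_pen) * t_of(wc) + (1 - wob_pen) * t_of(wob)
  }
  W
}

test_that("codon counting and RCU follow the hand-counted examples", {
  cds <- Biostrings::DNAStringSet(c(g1 = "CCTCCTCCC", g2 = "AAA"))
  cc <- count_codons(cds, trim_trailing_stop = FALSE)
  expect_equal(unname(cc["g1", "CCT"]), 2L)
  expect_equal(unname(cc["g1", "CCC"]), 1L)
  rcu <- relative_codon_usage(cc[1L, , drop = FALSE])
  expect_equal(unname(rcu["CCT"]), 2 / 3)
  expect_equal(unname(rcu["CCC"]), 1 / 3)
  # single-codon gene: RCU 1 within its family
  rcu2 <- relative_codon_usage(cc[2L, , drop = FALSE])
  expect_equal(unname(rcu2["AAA"]), 1)
  # family sums are 1 wherever defined
  ct <- codon_table(); sense <- ct[!ct$is_stop, ]
  sums <- tapply(rcu[sense$codon], sense$amino_acid, sum)
  expect_true(all(is.na(sums) | abs(sums - 1) < 1e-12))

  expect_warning(count_codons(Biostrings::DNAStringSet(c(bad = "CCTCC",
                                                         ok = "AAA")),
                              trim_trailing_stop = FALSE),
                 "not divisible by 3")
  expect_error(suppressWarnings(
    count_codons(Biostrings::DNAStringSet(c(bad = "CCTCC")))),
    "no usable")
})

test_that("trailing stop codons are trimmed from counts", {
  cc <- count_codons(Biostrings::DNAStringSet(c(g = "CCTTAA")))
  expect_equal(unname(cc["g", "TAA"]), 0L)
  expect_equal(unname(cc["g", "CCT"]), 1L)
})

test_that("tAI weights match the printed single-tRNA example", {
  tw <- tai_weights(c(AGG = 1))
  expect_equal(unname(tw$W[c("CCT", "CCC", "CCA", "CCG")]),
               c(1, 0.5, 0.25, 0))
  expect_equal(unname(tw$w["CCT"]), 1)
  # zeros replaced by the geometric mean of the nonzero weights
  expect_equal(tw$zero_replacement,
               exp(mean(log(c(1, 0.5, 0.25)))))
  expect_equal(unname(tw$w["CCG"]), tw$zero_replacement)
})

test_that("tAI weights equal the per-codon pairing-rule oracle", {
  set.seed(31)
  for (rep in 1:5) {
    t <- setNames(stats::rexp(64), all_anticodons())
    s <- default_s_vector()
    tw <- tai_weights(t, s)
    expect_equal(tw$W, tai_w_oracle(t, s), tolerance = 1e-12)
  }
  # and under a different s-vector
  s2 <- c(0.1, 0.2, 0, 0, 0.4, 0.3, 0.6, 0.5, 0.9)
  t <- setNames(stats::runif(64), all_anticodons())
  expect_equal(tai_weights(t, s2)$W, tai_w_oracle(t, s2), tolerance = 1e-12)
})

test_that("methionine is decoded by CAT only, with no U:G wobble term", {
  tw <- tai_weights(c(CAT = 1, TAT = 1))
  expect_equal(unname(tw$W["ATG"]), 1)          # no (1-s8)*t(TAT) term
  expect_gt(unname(tw$W["ATA"]), 0)             # TAT does decode Ile ATA
})

test_that("with no pairing penalty, uniform supply gives symmetric weights", {
  # all non-stop-decoding anticodons at abundance 1, s = 0: every codon is
  # reached by two decoders at full affinity (W = 2) except ATG (CAT only)
  # and TGG (whose U34 wobble decoder TCA is the selenocysteine/stop
  # anticodon, excluded from the supply)
  t <- setNames(rep(1, 64), all_anticodons())
  tw <- tai_weights(t, s = rep(0, 9))
  expect_equal(unname(tw$W[c("ATG", "TGG")]), c(1, 1))
  others <- setdiff(sense_codons(), c("ATG", "TGG"))
  expect_true(all(tw$W[others] == 2))
})

test_that("gene tAI is the geometric mean of codon weights", {
  tw <- tai_weights(c(AGG = 1))
  cc <- count_codons(Biostrings::DNAStringSet(
    c(g = "CCTCCC", gperm = "CCCCCT", one = "CCT")),
    trim_trailing_stop = FALSE)
  tai <- gene_tai(tw, cc)
  expect_equal(unname(tai["g"]), sqrt(0.5))
  expect_equal(unname(tai["gperm"]), unname(tai["g"]))   # order-invariant
  expect_equal(unname(tai["one"]), unname(tw$w["CCT"]))  # single codon
})

test_that("tAI on a 20-gene fixture matches direct-formula evaluation to 1e-9", {
  set.seed(77)
  t <- setNames(stats::rexp(64), all_anticodons())
  tw <- tai_weights(t)
  genes <- vapply(1:20, function(i) {
    paste(sample(sense_codons(), sample(30:80, 1L), replace = TRUE),
          collapse = "")
  }, "")
  names(genes) <- paste0("g", 1:20)
  cc <- count_codons(Biostrings::DNAStringSet(genes),
                     trim_trailing_stop = FALSE)
  got <- gene_tai(tw, cc)
  w_oracle <- tai_w_oracle(t, default_s_vector())
  w_oracle <- w_oracle / max(w_oracle)
  w_oracle[w_oracle == 0] <- exp(mean(log(w_oracle[w_oracle > 0])))
  expected <- vapply(names(genes), function(g) {
    cods <- substring(genes[[g]], seq(1, nchar(genes[[g]]), 3),
                      seq(3, nchar(genes[[g]]), 3))
    prod(w_oracle[cods])^(1 / length(cods))   # direct product, no log space
  }, 1.0)
  expect_equal(got, expected, tolerance = 1e-9)
})

test_that("relative weights peak at 1 per family and survive rescaling", {
  set.seed(13)
  t <- setNames(stats::rexp(64), all_anticodons())
  tw <- tai_weights(t)
  Rw <- relative_tai_weights(tw)
  ct <- codon_table(); sense <- ct[!ct$is_stop, ]
  fam_max <- tapply(Rw[sense$codon], sense$amino_acid, max)
  expect_true(all(abs(fam_max - 1) < 1e-12))
  # global rescaling of the tRNA pool leaves Rw untouched
  Rw2 <- relative_tai_weights(tai_weights(t * 7.3))
  expect_equal(Rw, Rw2, tolerance = 1e-12)
})

test_that("codon demand is the expression-weighted usage, family-normalized", {
  cds <- Biostrings::DNAStringSet(c(gene1 = "CCTCCT", gene2 = "CCCCCC"))
  cc <- count_codons(cds, trim_trailing_stop = FALSE)
  dem <- codon_demand(cc, c(gene1 = 10, gene2 = 5))
  expect_equal(unname(dem$CU[c("CCT", "CCC")]), c(20, 10))
  expect_equal(unname(dem$D[c("CCT", "CCC")]), c(1, 0.5))
  # scaling expression leaves D unchanged
  dem2 <- codon_demand(cc, c(gene1 = 10, gene2 = 5) * 100)
  expect_equal(dem$D, dem2$D)
  expect_error(codon_demand(cc, c(gene1 = 0, gene2 = 0)), "zero")
  expect_error(codon_demand(cc, c(other = 1)), "no shared")
})

test_that("SDAw covers 60 codons, flags zero demand, divides elementwise", {
  supply <- setNames(rep(1, 61), sense_codons())
  demand <- setNames(rep(1, 61), sense_codons())
  sdaw <- sda_weights(supply, demand)
  expect_equal(length(sdaw), 60L)
  expect_false("ATG" %in% names(sdaw))
  expect_true(all(abs(sdaw - 1) < 1e-12))

  supply[c("CCT", "CCC", "CCA")] <- c(1, 0.5, 0.25)
  demand[c("CCT", "CCC", "CCA")] <- c(1, 0.5, 1)
  sdaw2 <- sda_weights(supply, demand)
  expect_equal(unname(sdaw2[c("CCT", "CCC", "CCA")]), c(1, 1, 0.25))

  demand["GGT"] <- 0
  sdaw3 <- sda_weights(supply, demand)
  expect_true(is.na(sdaw3["GGT"]))
  expect_true("GGT" %in% attr(sdaw3, "missing"))
})

test_that("gene SDA is the length-normalized product with Met/stop skipped", {
  sdaw <- setNames(rep(1, 60), sda_codons())
  sdaw[c("CCT", "CCC")] <- c(4, 1)
  cc <- count_codons(Biostrings::DNAStringSet(
    c(two = "CCTCCC", uni = "GGTGGTGGT", met = "ATGCCTATG")),
    trim_trailing_stop = FALSE)
  sda <- gene_sda(sdaw, cc)
  expect_equal(unname(sda["two"]), 2)               # sqrt(4*1)
  expect_equal(unname(sda["uni"]), unname(sdaw["GGT"]))
  expect_equal(unname(sda["met"]), 4)               # ATG skipped entirely
  # geometric-mean bounds
  set.seed(3)
  sdaw_r <- setNames(stats::rexp(60), sda_codons())
  genes <- vapply(1:10, function(i)
    paste(sample(sda_codons(), 40, replace = TRUE), collapse = ""), "")
  names(genes) <- paste0("g", 1:10)
  ccr <- count_codons(Biostrings::DNAStringSet(genes),
                      trim_trailing_stop = FALSE)
  scores <- gene_sda(sdaw_r, ccr)
  for (g in names(genes)) {
    cods <- unique(substring(genes[[g]], seq(1, 118, 3), seq(3, 120, 3)))
    expect_gte(scores[[g]], min(sdaw_r[cods]) - 1e-12)
    expect_lte(scores[[g]], max(sdaw_r[cods]) + 1e-12)
  }
})

test_that("supply proportional to demand gives SDAw and gene SDA of 1", {
  set.seed(8)
  t <- setNames(stats::rexp(64), all_anticodons())
  Rw <- relative_tai_weights(tai_weights(t))
  sdaw <- sda_weights(Rw, setNames(Rw[sda_codons()], sda_codons()))
  expect_true(all(abs(sdaw - 1) < 1e-12, na.rm = TRUE))
  cc <- count_codons(Biostrings::DNAStringSet(
    c(g = paste(sample(sda_codons(), 50, replace = TRUE), collapse = ""))),
    trim_trailing_stop = FALSE)
  expect_equal(unname(gene_sda(sdaw, cc)["g"]), 1, tolerance = 1e-12)
})

test_that("SDAw and RtAI are invariant to global rescaling of both inputs", {
  fx <- sim_ref_fixture()
  truth <- dispersed_truth(fx$clusters)
  sim <- simulate_reads(fx$cfg, fx$clusters, truth)
  prof <- quantify_sample(NULL, sim$mature_hits, fx$clusters)
  set.seed(21)
  genes <- vapply(1:15, function(i)
    paste(sample(sense_codons(), 50, replace = TRUE), collapse = ""), "")
  names(genes) <- paste0("g", seq_along(genes))
  cc <- count_codons(Biostrings::DNAStringSet(genes),
                     trim_trailing_stop = FALSE)
  expr <- setNames(stats::rlnorm(length(genes)), names(genes))

  res1 <- sda_pipeline(prof, cc, expr)
  # rescale the tRNA pool (scale sqrt-RPM by scaling counts is not global;
  # instead feed scaled supply directly through the weight chain)
  sup <- sqrt_normalize(prof)
  tw_scaled <- tai_weights(sup * 11)
  Rw_scaled <- relative_tai_weights(tw_scaled)
  dem_scaled <- codon_demand(cc, expr * 0.037)
  sdaw_scaled <- sda_weights(Rw_scaled, dem_scaled)
  expect_equal(setNames(res1$weights$SDAw, res1$weights$codon)[sda_codons()],
               sdaw_scaled[sda_codons()], tolerance = 1e-12)
  rtai_scaled <- gene_geometric_score(Rw_scaled, cc)
  expect_equal(setNames(res1$genes$RtAI, res1$genes$gene_id),
               rtai_scaled, tolerance = 1e-12)
})
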