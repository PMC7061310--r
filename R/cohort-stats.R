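#' Differential feature testing between two sample groups
#'
#' Per feature: the log2 ratio of group medians and an unpaired two-tailed
#' Wilcoxon rank-sum test (exact where possible, normal approximation with
#' mid-ranks under ties), with Benjamini-Hochberg correction across
#' features. Features where both groups are a single constant value are
#' flagged degenerate with p = 1.
#'
#' @param matrix Numeric samples x features matrix (rownames = sample ids).
#' @param groups Character/factor vector of group labels per sample.
#' @param group_a,group_b Labels of the reference and comparison groups;
#'   `log2fc = log2(median_b / median_a)`.
#' @return Data.frame: `feature`, `log2fc`, `p`, `q`, `n_a`, `n_b`,
#'   `degenerate`.
#' @export
differential <- function(matrix, groups, group_a, group_b) {
  stopifnot(nrow(matrix) == length(groups))
  if (anyDuplicated(rownames(matrix)))
    stop("duplicated sample ids")
  res <- lapply(colnames(matrix), function(f) {
    xa <- matrix[groups == group_a, f]
    xb <- matrix[groups == group_b, f]
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    if (length(xa) < 2L || length(xb) < 2L)
      stop("fewer than 2 samples per group for feature ", f)
    degen <- length(unique(c(xa, xb))) == 1L
    p <- if (degen) 1 else
      suppressWarnings(wilcox.test(xb, xa, alternative = "two.sided")$p.value)
    ma <- median(xa); mb <- median(xb)
    lfc <- if (ma > 0 && mb > 0) log2(mb / ma) else NA_real_
    data.frame(feature = f, log2fc = lfc, p = p,
               n_a = length(xa), n_b = length(xb), degenerate = degen,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- p.adjust(out$p, method = "BH")
  out[, c("feature", "log2fc", "p", "q", "n_a", "n_b", "degenerate")]
}

.genes_granges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
}

#' Promoter methylation of tRNA genes and isoacceptors
#'
#' Averages methylation beta values over a strand-aware window per gene.
#' In `array` mode the window runs from 1.5 kb upstream of the TSS (5' of
#' the gene on its strand) to the gene end, matching sparse array probes;
#' in `bisulfite` mode it is restricted to the gene body, appropriate for
#' dense coverage of Pol-III genes whose promoter elements are intragenic.
#' Isoacceptor values are the mean over member genes sharing an anticodon.
#'
#' @param genes A `trna_genes` data.frame.
#' @param betas Data.frame with columns `chrom`, `pos` (1-based position)
#'   and one numeric beta column per sample.
#' @param mode `"array"` or `"bisulfite"`.
#' @param upstream Window extension upstream of the TSS in `array` mode
#'   (default 1500).
#' @return List with `gene` (genes x samples matrix, `NA` where no
#'   positions fall in the window), `isoacceptor` (anticodons x samples),
#'   and `coverage` (fraction of genes with at least one position).
#' @export
promoter_methylation <- function(genes, betas, mode = c("array", "bisulfite"),
                                 upstream = 1500L) {
  mode <- match.arg(mode)
  gr <- .genes_granges(genes)
  win <- if (mode == "array") {
    GenomicRanges::punion(
      GenomicRanges::promoters(gr, upstream = upstream, downstream = 0L),
      gr)
  } else gr
  samples <- setdiff(names(betas), c("chrom", "pos"))
  probes <- GenomicRanges::GRanges(
    seqnames = betas$chrom,
    ranges = IRanges::IRanges(start = betas$pos, width = 1L))
  ov <- GenomicRanges::findOverlaps(win, probes, ignore.strand = TRUE)
  gmat <- matrix(NA_real_, nrow = nrow(genes), ncol = length(samples),
                 dimnames = list(genes$gene_id, samples))
  for (s in samples) {
    v <- tapply(betas[[s]][S4Vectors::subjectHits(ov)],
                S4Vectors::queryHits(ov), mean, na.rm = TRUE)
    gmat[as.integer(names(v)), s] <- as.numeric(v)
  }
  iso <- .isoacceptor_mean(gmat, genes$anticodon)
  list(gene = gmat, isoacceptor = iso,
       coverage = mean(rowSums(!is.na(gmat)) > 0))
}

#' Overlap-weighted copy number of tRNA genes and isoacceptors
#'
#' Projects piecewise-constant segmented copy-number values (log2(CN)-1
#' scale) onto genes: a gene fully inside one segment takes that value;
#' genes spanning segments take the overlap-length-weighted mean; genes
#' outside all segments are missing. Isoacceptor values are the mean over
#' member genes.
#'
#' @param genes A `trna_genes` data.frame.
#' @param segments Data.frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive, SEG-like) and one numeric value column per
#'   sample.
#' @return List with `gene` (genes x samples matrix) and `isoacceptor`
#'   (anticodons x samples).
#' @export
gene_cna <- function(genes, segments) {
  gr <- .genes_granges(genes)
  samples <- setdiff(names(segments), c("chrom", "start", "end"))
  seg <- GenomicRanges::GRanges(
    seqnames = segments$chrom,
    ranges = IRanges::IRanges(start = segments$start, end = segments$end))
  ov <- GenomicRanges::findOverlaps(gr, seg, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  w <- GenomicRanges::width(GenomicRanges::pintersect(gr[qh], seg[sh],
                                                      ignore.strand = TRUE))
  gmat <- matrix(NA_real_, nrow = nrow(genes), ncol = length(samples),
                 dimnames = list(genes$gene_id, samples))
  for (s in samples) {
    num <- tapply(w * segments[[s]][sh], qh, sum, na.rm = TRUE)
    den <- tapply(w, qh, sum)
    gmat[as.integer(names(num)), s] <- as.numeric(num) / as.numeric(den)
  }
  list(gene = gmat, isoacceptor = .isoacceptor_mean(gmat, genes$anticodon))
}

.isoacceptor_mean <- function(gmat, anticodon) {
  acs <- sort(unique(anticodon))
  out <- matrix(NA_real_, nrow = length(acs), ncol = ncol(gmat),
                dimnames = list(acs, colnames(gmat)))
  for (a in acs) {
    sub <- gmat[anticodon == a, , drop = FALSE]
    m <- colMeans(sub, na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    out[a, ] <- m
  }
  out
}

#' Per-isoacceptor multiple linear regression on methylation and copy number
#'
#' Fits, for every isoacceptor within every condition, the ordinary
#' least-squares model `abundance = b0 + bMe * Me + bCNA * CNA` where the
#' dependent variable is the sqrt-normalized tRNA abundance. Only complete
#' samples enter a fit; models with fewer than `p + 2 = 4` complete
#' samples or a rank-deficient design are skipped with a flag.
#' Coefficient t-statistic p-values are FDR-corrected jointly across the
#' Me and CNA coefficients of all fitted models.
#'
#' @param data Long data.frame with columns `isoacceptor`, `condition`,
#'   `sample`, `abundance`, `me`, `cna`.
#' @return Data.frame with one row per (isoacceptor, condition):
#'   coefficients `b0`, `bMe`, `bCNA`, standard errors `se_me`, `se_cna`,
#'   p-values `p_me`, `p_cna`, FDR-adjusted `q_me`, `q_cna`, `r2`, `n`,
#'   `fitted`, `skip_reason`.
#' @export
fit_isoacceptor_mlr <- function(data) {
  need <- c("isoacceptor", "condition", "sample", "abundance", "me", "cna")
  stopifnot(all(need %in% names(data)))
  combos <- unique(data[, c("isoacceptor", "condition")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    iso <- combos$isoacceptor[i]; cond <- combos$condition[i]
    d <- data[data$isoacceptor == iso & data$condition == cond,
              c("abundance", "me", "cna")]
    d <- d[complete.cases(d), , drop = FALSE]
    base <- data.frame(isoacceptor = iso, condition = cond,
                       b0 = NA_real_, bMe = NA_real_, bCNA = NA_real_,
                       se_me = NA_real_, se_cna = NA_real_,
                       p_me = NA_real_, p_cna = NA_real_, r2 = NA_real_,
                       n = nrow(d), fitted = FALSE,
                       skip_reason = NA_character_,
                       stringsAsFactors = FALSE)
    if (nrow(d) < 4L) {
      base$skip_reason <- "insufficient_samples"
      return(base)
    }
    X <- cbind(1, d$me, d$cna)
    if (qr(X)$rank < 3L) {
      base$skip_reason <- "rank_deficient"
      return(base)
    }
    fit <- lm(abundance ~ me + cna, data = d)
    sm <- summary(fit)
    cf <- sm$coefficients
    base$b0 <- cf["(Intercept)", 1L]
    base$bMe <- cf["me", 1L]; base$bCNA <- cf["cna", 1L]
    base$se_me <- cf["me", 2L]; base$se_cna <- cf["cna", 2L]
    base$p_me <- cf["me", 4L]; base$p_cna <- cf["cna", 4L]
    base$r2 <- sm$r.squared
    base$fitted <- TRUE
    base
  })
  out <- do.call(rbind, rows)
  # joint FDR over all coefficient p-values of all fitted models
  pv <- c(out$p_me, out$p_cna)
  qv <- rep(NA_real_, length(pv))
  ok <- !is.na(pv)
  qv[ok] <- p.adjust(pv[ok], method = "BH")
  out$q_me <- qv[seq_len(nrow(out))]
  out$q_cna <- qv[nrow(out) + seq_len(nrow(out))]
  attr(out, "fdr_scope") <- "all coefficients of all fitted models, jointly"
  out
}

#' Two-sided binomial test on significant coefficient signs
#'
#' Counts positive and negative coefficients among the FDR-significant
#' fits and tests the sign balance against 0.5 with an exact two-tailed
#' binomial test.
#'
#' @param results Output of [fit_isoacceptor_mlr()].
#' @param which `"me"` or `"cna"`.
#' @param alpha FDR threshold selecting coefficients (default 0.05).
#' @return List with `n_pos`, `n_neg`, `p` (`NA` with a flag when no
#'   coefficient is significant).
#' @export
coefficient_sign_test <- function(results, which = c("me", "cna"),
                                  alpha = 0.05) {
  which <- match.arg(which)
  beta <- results[[if (which == "me") "bMe" else "bCNA"]]
  q <- results[[paste0("q_", which)]]
  sig <- !is.na(q) & q < alpha
  n_pos <- sum(sig & beta > 0); n_neg <- sum(sig & beta < 0)
  if (n_pos + n_neg == 0L) {
    return(list(n_pos = 0L, n_neg = 0L, p = NA_real_,
                flag = "no_significant_coefficients"))
  }
  p <- binom.test(n_pos, n_pos + n_neg, p = 0.5,
                  alternative = "two.sided")$p.value
  list(n_pos = n_pos, n_neg = n_neg, p = p, flag = NA_character_)
}

#' Survival stratification by SDAw
#'
#' Splits patients into low/high groups as the bottom and top `fraction`
#' (default 40%) of the SDAw distribution (middle excluded; ties at the
#' quantile boundary broken by stable input order), estimates the
#' product-limit survival curve per group and compares them with a
#' two-group log-rank test.
#'
#' @param sdaw Named numeric vector of per-patient SDAw (names = patient
#'   ids matching `clinical$patient`).
#' @param clinical Data.frame with columns `patient`, `time`, `event`
#'   (1 = death, 0 = censored).
#' @param fraction Quantile fraction per group (default 0.4).
#' @return List with `groups` (data.frame patient, group), `fit` (a
#'   [survival::survfit] object), `logrank_p`, `n_low`, `n_high`.
#' @export
survival_by_sdaw <- function(sdaw, clinical, fraction = 0.4) {
  stopifnot(fraction > 0, fraction <= 0.5)
  stopifnot(all(clinical$time >= 0))
  common <- intersect(names(sdaw), clinical$patient)
  if (!length(common)) stop("no patients shared between sdaw and clinical")
  sdaw <- sdaw[common]
  k <- floor(length(sdaw) * fraction)
  if (k < 1L) stop("a group with zero patients")
  ord <- order(sdaw)            # stable for ties
  low <- common[ord[seq_len(k)]]
  high <- common[ord[seq.int(length(sdaw) - k + 1L, length(sdaw))]]
  grp <- data.frame(patient = c(low, high),
                    group = rep(c("low", "high"), c(k, k)),
                    stringsAsFactors = FALSE)
  cl <- merge(grp, clinical, by = "patient", sort = FALSE)
  cl$group <- factor(cl$group, levels = c("low", "high"))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = cl)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = cl)
  p <- as.numeric(1 - pchisq(sd$chisq, df = 1L))
  list(groups = grp, fit = fit, logrank_p = p,
       n_low = k, n_high = k)
}

#' Select codons for the survival scan from differential results
#'
#' Given per-condition differential SDAw results, a codon becomes a
#' survival candidate when the absolute difference between the number of
#' conditions where it is significantly up and significantly down exceeds
#' `min_margin` (default 5).
#'
#' @param diff_list Named list (one element per condition) of
#'   [differential()] outputs over the same codon features.
#' @param alpha FDR threshold for per-condition significance.
#' @param min_margin Required `|n_up - n_down|` margin.
#' @return Character vector of candidate codon features.
#' @export
select_survival_codons <- function(diff_list, alpha = 0.05, min_margin = 5L) {
  tab <- do.call(rbind, lapply(diff_list, function(d) {
    data.frame(feature = d$feature,
               up = d$q < alpha & !is.na(d$log2fc) & d$log2fc > 0,
               down = d$q < alpha & !is.na(d$log2fc) & d$log2fc < 0)
  }))
  agg_up <- tapply(tab$up, tab$feature, sum)
  agg_down <- tapply(tab$down, tab$feature, sum)
  feats <- names(agg_up)
  feats[abs(agg_up - agg_down[feats]) > min_margin]
}

#' Survival scan over candidate codons
#'
#' Runs [survival_by_sdaw()] for each candidate codon column of a
#' patients x codons SDAw matrix and FDR-corrects the log-rank p-values
#' across codons.
#'
#' @param sdaw_matrix Patients x codons numeric matrix (rownames =
#'   patient ids).
#' @param clinical Clinical table as in [survival_by_sdaw()].
#' @param codons Candidate codons (e.g. from [select_survival_codons()]).
#' @param fraction Group fraction.
#' @return Data.frame: `codon`, `logrank_p`, `q`.
#' @export
survival_codon_scan <- function(sdaw_matrix, clinical, codons,
                                fraction = 0.4) {
  res <- lapply(codons, function(cod) {
    sv <- survival_by_sdaw(setNames(sdaw_matrix[, cod],
                                    rownames(sdaw_matrix)),
                           clinical, fraction = fraction)
    data.frame(codon = cod, logrank_p = sv$logrank_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- p.adjust(out$logrank_p, method = "BH")
  out
}
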