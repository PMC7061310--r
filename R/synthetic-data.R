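#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators with the defaults
#' used throughout the test suite. Identical config plus seed yields
#' byte-identical outputs.
#'
#' @param seed Integer seed driving all randomness.
#' @param anticodon_panel Anticodons covered by the toy reference.
#' @param n_genes Number of tRNA genes (>= panel size).
#' @param intron_prob Probability that a gene carries an intron.
#' @param flank_len Pre-tRNA flank width.
#' @param read_depth Number of mature-tRNA reads to draw.
#' @param error_rate Per-base sequencing error probability.
#' @param min_read_len,max_read_len Fragment length range.
#' @param flank_read_fraction,genomic_read_fraction Extra first-pass reads
#'   drawn from pre-tRNA flanks / masked-genome background, as fractions
#'   of `read_depth`.
#' @param planted_modifications Data.frame (`anticodon`, `model_position`,
#'   `fraction`) of misincorporation sites to plant, or `NULL`.
#' @param expression_meanlog,expression_sdlog Log-normal expression model.
#' @param regression_truth Named list `b0`, `bMe`, `bCNA`, `sigma`.
#' @param survival_truth Named list `hazard_ratio`, `baseline_hazard`,
#'   `censoring_rate`.
#' @param n_conditions,n_per_group,n_regression_samples,n_patients Cohort
#'   sizes.
#' @param sdaw_shift Multiplicative SDAw shift injected into the tumor
#'   group for `shift_codons`.
#' @param shift_codons Codons receiving the injected shift.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       anticodon_panel = c("AGG", "TGG", "CGG",
                                           "GCC", "TCC", "CCC",
                                           "AGC", "TGC", "GAA"),
                       n_genes = 16L,
                       intron_prob = 0.25,
                       flank_len = 50L,
                       read_depth = 20000L,
                       error_rate = 0.001,
                       min_read_len = 25L,
                       max_read_len = 45L,
                       flank_read_fraction = 0.05,
                       genomic_read_fraction = 0.05,
                       planted_modifications = NULL,
                       expression_meanlog = 2,
                       expression_sdlog = 1,
                       regression_truth = list(b0 = 2, bMe = -3,
                                               bCNA = 1.5, sigma = 0.1),
                       survival_truth = list(hazard_ratio = 3,
                                             baseline_hazard = 0.02,
                                             censoring_rate = 0.2),
                       n_conditions = 1L,
                       n_per_group = 50L,
                       n_regression_samples = 30L,
                       n_patients = 200L,
                       sdaw_shift = 2,
                       shift_codons = c("CCA", "GGT")) {
  stopifnot(intron_prob >= 0, intron_prob <= 1,
            error_rate >= 0, error_rate <= 1,
            read_depth >= 0, n_genes >= length(anticodon_panel))
  structure(as.list(environment()), class = "sim_config")
}

.SUBST <- c(A = "G", G = "A", C = "T", T = "C")

# Deterministic family-identity mutations: each anticodon family differs
# from the template at 3 stem positions, so isoacceptors are separable
# by more than the anticodon alone (as real tRNA families are).
.family_seq <- function(anticodon, fam_index, template = trna_model_template()) {
  body <- substr(template$seq, 1L, 73L)
  ch <- strsplit(body, "")[[1L]]
  ch[34:36] <- strsplit(anticodon, "")[[1L]]
  stem_pos <- c(10:13, 22:25, 27:31, 39:43, 49:53, 61:65)
  idx <- stem_pos[((fam_index - 1L) * 3L + 0:2) %% length(stem_pos) + 1L]
  ch[idx] <- .SUBST[ch[idx]]
  paste(ch, collapse = "")
}

.random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Simulate a toy genome and tRNA annotation
#'
#' Builds template-derived tRNA genes covering the configured anticodon
#' panel, each family distinguished by stem mutations and isodecoders
#' within a family by a V-region substitution. The gene set contains at
#' least one identical-sequence duplicate pair and (at the default intron
#' probability, when `n_genes` permits) intron-bearing genes with the
#' intron inserted after structural position 37. Genes are embedded on
#' both strands of a toy chromosome separated by random spacers.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory; when given, `genome.fa` and a
#'   tRNAscan-SE-style `trnas.txt` are written there.
#' @return List with `genome` (DNAStringSet), `annotation` (path or
#'   in-memory lines), `genes` (truth data.frame: gene_id, anticodon,
#'   gene_seq, mature_seq, has_intron).
#' @export
simulate_reference <- function(config, dir = NULL) {
  set.seed(config$seed)
  panel <- config$anticodon_panel
  n <- config$n_genes
  ac_of_gene <- panel[(seq_len(n) - 1L) %% length(panel) + 1L]
  fam_index <- match(ac_of_gene, panel)

  gene_seqs <- character(n)
  has_intron <- logical(n)
  intron_seq <- character(n)
  iso_variant <- stats::ave(seq_len(n), ac_of_gene, FUN = seq_along)
  for (i in seq_len(n)) {
    base <- .family_seq(ac_of_gene[i], fam_index[i])
    if (iso_variant[i] == 2L && i == which(ac_of_gene == ac_of_gene[1L])[2L]) {
      # guaranteed duplicate pair: second gene of the first anticodon
      gene_seqs[i] <- gene_seqs[which(ac_of_gene == ac_of_gene[1L])[1L]]
      has_intron[i] <- has_intron[which(ac_of_gene == ac_of_gene[1L])[1L]]
      intron_seq[i] <- intron_seq[which(ac_of_gene == ac_of_gene[1L])[1L]]
      next
    }
    if (iso_variant[i] > 1L) {
      ch <- strsplit(base, "")[[1L]]
      vpos <- 44L + (iso_variant[i] - 2L) %% 5L
      ch[vpos] <- .SUBST[ch[vpos]]
      base <- paste(ch, collapse = "")
    }
    has_intron[i] <- runif(1) < config$intron_prob
    if (has_intron[i]) {
      intron_seq[i] <- .random_dna(sample(12:18, 1L))
      gene_seqs[i] <- paste0(substr(base, 1L, 37L), intron_seq[i],
                             substr(base, 38L, nchar(base)))
    } else {
      gene_seqs[i] <- base
    }
  }

  strand <- rep(c("+", "-"), length.out = n)
  chrom_parts <- character(2L * n + 1L)
  chrom_parts[1L] <- .random_dna(sample(60:120, 1L))
  starts <- integer(n); ends <- integer(n)
  cursor <- nchar(chrom_parts[1L])
  for (i in seq_len(n)) {
    gseq <- if (strand[i] == "+") gene_seqs[i] else revcomp(gene_seqs[i])
    starts[i] <- cursor
    ends[i] <- cursor + nchar(gseq)
    chrom_parts[2L * i] <- gseq
    chrom_parts[2L * i + 1L] <- .random_dna(sample(60:120, 1L))
    cursor <- ends[i] + nchar(chrom_parts[2L * i + 1L])
  }
  genome <- Biostrings::DNAStringSet(paste(chrom_parts, collapse = ""))
  names(genome) <- "chr1"

  aa <- anticodon_aa(ac_of_gene)
  rows <- character(n)
  for (i in seq_len(n)) {
    if (strand[i] == "+") {
      b <- starts[i] + 1L; e <- ends[i]
      if (has_intron[i]) {
        ib <- starts[i] + 37L + 1L
        ie <- starts[i] + 37L + nchar(intron_seq[i])
      } else { ib <- 0L; ie <- 0L }
    } else {
      b <- ends[i]; e <- starts[i] + 1L
      if (has_intron[i]) {
        ib <- ends[i] - 37L
        ie <- ends[i] - 37L - nchar(intron_seq[i]) + 1L
      } else { ib <- 0L; ie <- 0L }
    }
    rows[i] <- paste("chr1", i, b, e, aa[i], ac_of_gene[i], ib, ie, "50.0",
                     sep = "\t")
  }

  mature <- vapply(seq_len(n), function(i) {
    body <- if (has_intron[i]) {
      paste0(substr(gene_seqs[i], 1L, 37L),
             substr(gene_seqs[i], 38L + nchar(intron_seq[i]),
                    nchar(gene_seqs[i])))
    } else gene_seqs[i]
    paste0(body, "CCA")
  }, "")
  genes <- data.frame(
    gene_id = sprintf("chr1.tRNA%d-%s%s", seq_len(n), aa, ac_of_gene),
    anticodon = ac_of_gene, amino_acid = aa, strand = strand,
    gene_seq = gene_seqs, mature_seq = mature, has_intron = has_intron,
    stringsAsFactors = FALSE
  )

  annotation <- rows
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(genome, file.path(dir, "genome.fa"))
    writeLines(rows, file.path(dir, "trnas.txt"))
    annotation <- file.path(dir, "trnas.txt")
  } else {
    annotation <- tempfile(fileext = ".txt")
    writeLines(rows, annotation)
  }
  list(genome = genome, annotation = annotation, genes = genes)
}

#' Simulate small-RNA reads over a mature library
#'
#' Draws reads multinomially from the configured true isoacceptor
#' abundances, fragments them, plants misincorporation sites at declared
#' consensus-model positions, adds sequencing errors, and emulates a
#' best-stratum aligner: every cluster matching a read at its originating
#' offset with the minimal mismatch count becomes a hit. Optional
#' pre-tRNA-flank and masked-genome reads exercise the first-pass filter.
#'
#' @param config A [sim_config()].
#' @param clusters A `trna_clusters` data.frame.
#' @param true_abundances Named numeric vector over anticodons, summing
#'   to 1.
#' @param pretrna Pre-tRNA table (needed for flank reads and first-pass
#'   records), or `NULL`.
#' @param masked_genome Masked genome DNAStringSet (needed for genomic
#'   reads), or `NULL`.
#' @param dir Optional directory; when given, `first.sam` and
#'   `mature.sam` are written there.
#' @return List with `first_hits`, `mature_hits` (hit tables as from
#'   [read_sam_hits()]), `truth` (read_id, origin, anticodon, cluster,
#'   modified), and `sam_paths` when `dir` is given.
#' @export
simulate_reads <- function(config, clusters, true_abundances,
                           pretrna = NULL, masked_genome = NULL,
                           dir = NULL) {
  stopifnot(abs(sum(true_abundances) - 1) < 1e-8)
  set.seed(config$seed)
  n <- config$read_depth
  if (n == 0L) {
    empty <- data.frame(read_id = character(0), target = character(0),
                        pos = integer(0), cigar = character(0),
                        nm = integer(0), seq = character(0),
                        secondary = logical(0), stringsAsFactors = FALSE)
    return(list(first_hits = empty, mature_hits = empty,
                truth = data.frame()))
  }
  acs <- names(true_abundances)
  stopifnot(all(acs %in% clusters$anticodon))
  n_per_ac <- as.vector(stats::rmultinom(1L, n, true_abundances))

  cl_seqs <- clusters$mature_seq
  names(cl_seqs) <- clusters$cluster_id
  cl_len <- nchar(cl_seqs)

  mods <- config$planted_modifications
  true_ac <- rep(acs, n_per_ac)
  read_cluster <- unlist(lapply(seq_along(acs), function(ai) {
    members <- clusters$cluster_id[clusters$anticodon == acs[ai]]
    if (length(members) == 1L) rep(members, n_per_ac[ai])
    else sample(members, n_per_ac[ai], replace = TRUE)
  }))
  len_cap <- cl_len[read_cluster]
  len_range <- seq.int(config$min_read_len, config$max_read_len)
  read_len <- pmin(
    if (length(len_range) == 1L) rep(len_range, n)
    else sample(len_range, n, replace = TRUE),
    len_cap)
  read_start <- as.integer(floor(runif(n) * (len_cap - read_len + 1L)))
  read_seq <- substr(cl_seqs[read_cluster], read_start + 1L,
                     read_start + read_len)
  read_mod <- logical(n)
  if (!is.null(mods)) {
    for (mi in seq_len(nrow(mods))) {
      off <- mods$model_position[mi] - 1L  # template-built: offset = pos-1
      flip <- true_ac == mods$anticodon[mi] &
        off >= read_start & off < read_start + read_len &
        runif(n) < mods$fraction[mi]
      if (any(flip)) {
        k <- off - read_start[flip] + 1L
        b <- substr(read_seq[flip], k, k)
        sub <- read_seq[flip]
        substr(sub, k, k) <- .SUBST[b]
        read_seq[flip] <- sub
        read_mod <- read_mod | flip
      }
    }
  }
  if (config$error_rate > 0) {
    nerr <- rbinom(n, read_len, config$error_rate)
    for (i in which(nerr > 0L)) {
      ch <- strsplit(read_seq[i], "")[[1L]]
      pos <- sample.int(read_len[i], nerr[i])
      ch[pos] <- vapply(ch[pos], function(b) {
        sample(setdiff(DNA_BASES, b), 1L)
      }, "")
      read_seq[i] <- paste(ch, collapse = "")
    }
  }
  read_id <- sprintf("read%06d", seq_len(n))

  # best-stratum hits, grouped over unique (start, len, seq) signatures
  sig <- paste(read_start, read_len, read_seq, sep = ":")
  uniq <- !duplicated(sig)
  hit_cache <- new.env(parent = emptyenv())
  for (i in which(uniq)) {
    s0 <- read_start[i]; L <- read_len[i]
    cand <- which(cl_len >= s0 + L)
    subs <- substr(cl_seqs[cand], s0 + 1L, s0 + L)
    rint <- utf8ToInt(read_seq[i])
    mm <- vapply(subs, function(x) sum(utf8ToInt(x) != rint), 1L)
    best <- min(mm)
    hits <- if (best <= 3L) names(cl_seqs)[cand[mm == best]] else character(0)
    assign(sig[i], list(targets = hits, nm = best), envir = hit_cache)
  }
  hit_of <- lapply(sig, get, envir = hit_cache)
  nh <- vapply(hit_of, function(h) length(h$targets), 1L)
  mature_hits <- data.frame(
    read_id = rep(read_id, nh),
    target = unlist(lapply(hit_of, `[[`, "targets")),
    pos = rep(read_start + 1L, nh),
    cigar = rep(paste0(read_len, "M"), nh),
    nm = rep(vapply(hit_of, `[[`, 1L, "nm"), nh),
    seq = rep(read_seq, nh),
    secondary = unlist(lapply(nh, function(k) seq_len(k) > 1L)),
    stringsAsFactors = FALSE
  )

  # first-pass records: mature-body reads mapped onto pre-tRNA contigs
  first_rows <- list()
  truth_extra <- list()
  if (!is.null(pretrna)) {
    memb1 <- vapply(clusters$member_gene_ids, `[`, "", 1L)
    gene_of_cluster <- setNames(memb1, clusters$cluster_id)
    pre_name <- paste0("pre_", pretrna$gene_id)
    pre_len <- nchar(pretrna$seq)
    gene_body_len <- pre_len - pretrna$flank5 - pretrna$flank3
    mature_body_len <- cl_len[read_cluster] - 3L  # without CCA tail
    ilen <- gene_body_len[match(gene_of_cluster[read_cluster],
                                pretrna$gene_id)] - mature_body_len
    idx <- match(gene_of_cluster[read_cluster], pretrna$gene_id)
    end0 <- read_start + read_len
    pre_off <- ifelse(end0 <= 37L, read_start,
                      ifelse(read_start >= 37L, read_start + ilen, NA))
    ok <- !is.na(pre_off) & end0 <= mature_body_len  # junction/CCA reads unmapped
    if (any(ok)) {
      first_rows$mature <- data.frame(
        read_id = read_id[ok],
        target = pre_name[idx[ok]],
        pos = pretrna$flank5[idx[ok]] + pre_off[ok] + 1L,
        cigar = paste0(read_len[ok], "M"),
        nm = 0L, seq = read_seq[ok], secondary = FALSE,
        stringsAsFactors = FALSE
      )
    }
    nf <- round(config$flank_read_fraction * n)
    if (nf > 0L) {
      gi <- sample.int(nrow(pretrna), nf, replace = TRUE)
      L <- pmin(sample(seq.int(config$min_read_len, config$max_read_len),
                       nf, replace = TRUE), pretrna$flank5[gi])
      s0 <- vapply(seq_len(nf), function(j) {
        sample.int(max(1L, pretrna$flank5[gi[j]] - 5L), 1L) - 1L
      }, 1L)
      first_rows$flank <- data.frame(
        read_id = sprintf("flank%05d", seq_len(nf)),
        target = pre_name[gi], pos = s0 + 1L,
        cigar = paste0(L, "M"), nm = 0L,
        seq = substr(pretrna$seq[gi], s0 + 1L, s0 + L),
        secondary = FALSE, stringsAsFactors = FALSE
      )
      truth_extra$flank <- data.frame(
        read_id = first_rows$flank$read_id, origin = "flank",
        anticodon = NA_character_, cluster = NA_character_,
        modified = FALSE, stringsAsFactors = FALSE
      )
    }
  }
  if (!is.null(masked_genome)) {
    ng <- round(config$genomic_read_fraction * n)
    if (ng > 0L) {
      chrom <- as.character(masked_genome[[1L]])
      clean <- gregexpr("[ACGT]{60,}", chrom)[[1L]]
      blk <- sample.int(length(clean), ng, replace = TRUE)
      L <- sample(seq.int(config$min_read_len, config$max_read_len),
                  ng, replace = TRUE)
      s0 <- as.integer(clean[blk]) +
        vapply(seq_len(ng), function(j) {
          sample.int(attr(clean, "match.length")[blk[j]] - L[j], 1L) - 1L
        }, 1L)
      first_rows$genomic <- data.frame(
        read_id = sprintf("genomic%05d", seq_len(ng)),
        target = names(masked_genome)[1L], pos = s0,
        cigar = paste0(L, "M"), nm = 0L,
        seq = substring(chrom, s0, s0 + L - 1L),
        secondary = FALSE, stringsAsFactors = FALSE
      )
      truth_extra$genomic <- data.frame(
        read_id = first_rows$genomic$read_id, origin = "genomic",
        anticodon = NA_character_, cluster = NA_character_,
        modified = FALSE, stringsAsFactors = FALSE
      )
    }
  }
  first_hits <- if (length(first_rows)) do.call(rbind, first_rows) else NULL

  truth <- rbind(
    data.frame(read_id = read_id, origin = "mature", anticodon = true_ac,
               cluster = read_cluster, modified = read_mod,
               stringsAsFactors = FALSE),
    if (length(truth_extra)) do.call(rbind, truth_extra)
  )
  rownames(truth) <- NULL

  out <- list(first_hits = first_hits, mature_hits = mature_hits,
              truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    refs <- setNames(cl_len, clusters$cluster_id)
    out$sam_paths <- c(
      mature = write_sam(mature_hits, refs, file.path(dir, "mature.sam")),
      first = if (!is.null(first_hits)) {
        flens <- c(
          if (!is.null(pretrna))
            setNames(nchar(pretrna$seq), paste0("pre_", pretrna$gene_id)),
          if (!is.null(masked_genome))
            setNames(Biostrings::width(masked_genome), names(masked_genome))
        )
        write_sam(first_hits, flens, file.path(dir, "first.sam"))
      }
    )
  }
  out
}

#' Write a hit table as a SAM file
#'
#' @param hits Hit table (`read_id`, `target`, `pos`, `cigar`, `nm`,
#'   `seq`, `secondary`).
#' @param ref_lengths Named integer vector of reference lengths for the
#'   SAM header.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(hits, ref_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                   as.integer(ref_lengths)))
  body <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*\tNM:i:%d",
                  hits$read_id, ifelse(hits$secondary, 256L, 0L),
                  hits$target, hits$pos, hits$cigar, hits$seq,
                  ifelse(is.na(hits$nm), 0L, hits$nm))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Simulate cohort-level tables with declared effects
#'
#' Generates the inputs of the cohort statistics with known ground truth:
#' a healthy/tumor SDAw matrix with a multiplicative shift injected into
#' declared codons; a long regression table generated from the declared
#' linear model `abundance = b0 + bMe*Me + bCNA*CNA + N(0, sigma)` for
#' every isoacceptor in every condition; an expression table; and a
#' survival cohort with exponential event times at the declared hazard
#' ratio between SDAw-defined groups.
#'
#' @param config A [sim_config()].
#' @return List with `sdaw` (samples x codons matrix), `groups`,
#'   `regression` (long data.frame ready for [fit_isoacceptor_mlr()]),
#'   `expression`, `survival` (patient, time, event, sdaw), and `truth`.
#' @export
simulate_cohort <- function(config) {
  set.seed(config$seed)
  codons <- sda_codons()
  npg <- config$n_per_group
  base <- setNames(exp(rnorm(length(codons), 0, 0.3)), codons)
  healthy <- t(replicate(npg, base * exp(rnorm(length(codons), 0, 0.2))))
  shift <- setNames(rep(1, length(codons)), codons)
  shift[config$shift_codons] <- config$sdaw_shift
  tumor <- t(replicate(npg, base * shift * exp(rnorm(length(codons), 0, 0.2))))
  sdaw <- rbind(healthy, tumor)
  rownames(sdaw) <- sprintf("s%03d", seq_len(2L * npg))
  groups <- rep(c("healthy", "tumor"), each = npg)

  rt <- config$regression_truth
  isos <- all_anticodons()
  conds <- sprintf("cond%02d", seq_len(config$n_conditions))
  n_rs <- config$n_regression_samples
  reg <- expand.grid(isoacceptor = isos, condition = conds,
                     sample = sprintf("r%03d", seq_len(n_rs)),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  reg$me <- runif(nrow(reg))
  reg$cna <- rnorm(nrow(reg), 0, 0.5)
  reg$abundance <- rt$b0 + rt$bMe * reg$me + rt$bCNA * reg$cna +
    rnorm(nrow(reg), 0, rt$sigma)

  n_expr_genes <- 50L
  expression <- setNames(
    rlnorm(n_expr_genes, config$expression_meanlog, config$expression_sdlog),
    sprintf("G%03d", seq_len(n_expr_genes)))

  st <- config$survival_truth
  np <- config$n_patients
  psdaw <- setNames(exp(rnorm(np, 0, 0.5)), sprintf("p%03d", seq_len(np)))
  k <- floor(np * 0.4)
  ordp <- order(psdaw)
  grp <- rep("mid", np)
  grp[ordp[seq_len(k)]] <- "low"
  grp[ordp[seq.int(np - k + 1L, np)]] <- "high"
  rate <- ifelse(grp == "high", st$baseline_hazard * st$hazard_ratio,
                 st$baseline_hazard)
  t_event <- rexp(np, rate)
  cr <- st$censoring_rate
  t_cens <- if (cr > 0) {
    rexp(np, st$baseline_hazard * cr / (1 - cr))
  } else rep(Inf, np)
  surv <- data.frame(
    patient = names(psdaw),
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    sdaw = as.numeric(psdaw),
    true_group = grp,
    stringsAsFactors = FALSE
  )

  list(sdaw = sdaw, groups = groups, regression = reg,
       expression = expression, survival = surv,
       truth = list(sdaw_shift = shift, regression = rt, survival = st))
}
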