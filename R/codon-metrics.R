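#' Count codons in coding sequences
#'
#' Tallies in-frame codons per gene. Sequences whose length is not a
#' multiple of 3 are skipped with a warning; codons containing ambiguous
#' bases are not counted (the per-gene shortfall is available via the
#' `n_skipped_codons` attribute). A trailing stop codon is trimmed by
#' default so that stop usage does not enter downstream scores.
#'
#' @param cds A [Biostrings::DNAStringSet] or path to a CDS FASTA.
#' @param trim_trailing_stop Drop a terminal stop codon when present.
#' @return A genes x 64 integer matrix of class `codon_counts` (rownames =
#'   gene ids, colnames = codons).
#' @export
count_codons <- function(cds, trim_trailing_stop = TRUE) {
  cds <- .as_dna_set(cds)
  ok <- Biostrings::width(cds) %% 3L == 0L & Biostrings::width(cds) > 0L
  if (any(!ok)) {
    warning(sum(!ok), " sequence(s) with length not divisible by 3 skipped: ",
            paste(utils::head(names(cds)[!ok], 5L), collapse = ", "))
    cds <- cds[ok]
  }
  if (!length(cds)) stop("no usable coding sequences")
  m <- Biostrings::trinucleotideFrequency(cds, step = 3L)
  rownames(m) <- names(cds)
  trimmed <- rep(FALSE, length(cds))
  if (trim_trailing_stop) {
    last <- as.character(Biostrings::subseq(cds, Biostrings::width(cds) - 2L))
    stops <- codon_table()$codon[codon_table()$is_stop]
    trimmed <- last %in% stops
    if (any(trimmed)) {
      idx <- cbind(which(trimmed), match(last[trimmed], colnames(m)))
      m[idx] <- m[idx] - 1L
    }
  }
  attr(m, "n_skipped_codons") <-
    as.integer(Biostrings::width(cds) %/% 3L - trimmed - rowSums(m))
  class(m) <- c("codon_counts", class(m))
  m
}

#' Relative codon usage (RCU)
#'
#' The contribution of each sense codon within its synonymous family;
#' family values sum to 1. Computed on the pooled counts by default, or per
#' gene.
#'
#' @param counts A `codon_counts` matrix.
#' @param per_gene Return a genes x 61 matrix instead of the pooled vector.
#' @return Named numeric vector over the 61 sense codons (or a matrix).
#' @export
relative_codon_usage <- function(counts, per_gene = FALSE) {
  ct <- codon_table()
  sense <- ct[!ct$is_stop, ]
  fam <- sense$amino_acid
  one <- function(x) {
    x <- x[sense$codon]
    tot <- tapply(x, fam, sum)
    denom <- as.numeric(tot[fam])
    setNames(ifelse(denom > 0, x / denom, NA_real_), sense$codon)
  }
  if (per_gene) {
    t(apply(unclass(counts), 1L, one))
  } else {
    one(colSums(unclass(counts)))
  }
}

#' Default selective-constraint vector for wobble pairing
#'
#' The non-optimized s-values penalizing each codon-anticodon pairing
#' geometry: the first four entries (Watson-Crick pairings U:A, C:G, A:U,
#' G:C at the wobble position) are 0, the wobble pairings U:G, C:I, A:I and
#' G:U carry 0.5/0.5/0.75/0.5, and the ninth entry (prokaryotic lysidine
#' C:A decoding of ATA) is carried for completeness but not applied under
#' the eukaryotic rules.
#'
#' @return Numeric vector of length 9.
#' @export
default_s_vector <- function() c(0, 0, 0, 0, 0.5, 0.5, 0.75, 0.5, 0.5)

#' tAI weights from anticodon abundances under wobble rules
#'
#' For every codon box `XYN`, the four anticodon slots are the reverse
#' complements `A34 = rc(XYT)`, `G34 = rc(XYC)`, `U34 = rc(XYA)`,
#' `C34 = rc(XYG)`, and each codon's raw weight is the affinity-weighted
#' sum of the abundances `t` of the anticodons able to decode it:
#'
#' \deqn{W(XYT) = (1-s_1) t_{A34} + (1-s_5) t_{G34}}
#' \deqn{W(XYC) = (1-s_2) t_{G34} + (1-s_6) t_{A34}}
#' \deqn{W(XYA) = (1-s_3) t_{U34} + (1-s_7) t_{A34}}
#' \deqn{W(XYG) = (1-s_4) t_{C34} + (1-s_8) t_{U34}}
#'
#' with the methionine special case `W(ATG) = (1-s_4) t_{CAT}` (the U34
#' anticodon TAT reads Ile ATA, not Met) and stop codons excluded. Weights
#' are max-normalized to `w = W / max(W)`; zero weights are replaced by the
#' geometric mean of the nonzero `w` so that geometric-mean gene scores
#' remain defined.
#'
#' @param anticodon_abundance Named numeric vector of anticodon abundances
#'   (conventionally sqrt-RPM). Anticodons absent from the vector count as
#'   zero; stop-decoding anticodons and abundances attached to them are
#'   ignored.
#' @param s Selective-constraint 9-vector (see [default_s_vector()]).
#' @return Object of class `tai_weights`: list with `s`, `W` (61 sense
#'   codons), `w` (max-normalized, zeros replaced), `zero_replacement`,
#'   `n_zero_replaced`.
#' @export
tai_weights <- function(anticodon_abundance, s = default_s_vector()) {
  stopifnot(length(s) == 9L)
  if (any(anticodon_abundance < 0)) stop("negative anticodon abundance")
  if (length(anticodon_abundance) == 0L || all(anticodon_abundance == 0))
    stop("all-zero anticodon abundance")
  t_of <- function(ac) {
    v <- anticodon_abundance[ac]
    ifelse(is.na(v), 0, v)
  }
  # anticodons whose cognate codon is a stop never enter the supply
  stop_acs <- revcomp(codon_table()$codon[codon_table()$is_stop])
  anticodon_abundance[names(anticodon_abundance) %in% stop_acs] <- 0

  boxes <- as.vector(outer(DNA_BASES, DNA_BASES,
                           function(a, b) paste0(a, b)))
  W <- c()
  for (xy in boxes) {
    a34 <- revcomp(paste0(xy, "T")); g34 <- revcomp(paste0(xy, "C"))
    u34 <- revcomp(paste0(xy, "A")); c34 <- revcomp(paste0(xy, "G"))
    W[paste0(xy, "T")] <- (1 - s[1]) * t_of(a34) + (1 - s[5]) * t_of(g34)
    W[paste0(xy, "C")] <- (1 - s[2]) * t_of(g34) + (1 - s[6]) * t_of(a34)
    W[paste0(xy, "A")] <- (1 - s[3]) * t_of(u34) + (1 - s[7]) * t_of(a34)
    W[paste0(xy, "G")] <- (1 - s[4]) * t_of(c34) + (1 - s[8]) * t_of(u34)
  }
  W["ATG"] <- (1 - s[4]) * t_of("CAT")
  W <- W[sense_codons()]
  w <- W / max(W)
  zero <- w == 0
  geo <- exp(mean(log(w[!zero])))
  w[zero] <- geo
  structure(list(s = s, W = W, w = w, zero_replacement = geo,
                 n_zero_replaced = sum(zero)),
            class = "tai_weights")
}

#' @export
print.tai_weights <- function(x, ...) {
  cat(sprintf("tAI weights over %d sense codons (%d zero(s) replaced by %.4g)\n",
              length(x$w), x$n_zero_replaced, x$zero_replacement))
  invisible(x)
}

#' Per-gene geometric-mean score over codon weights
#'
#' Shared engine for tAI, RtAI and SDA gene scores: the length-normalized
#' product of per-codon weights, computed in log space. Codons outside the
#' weight vector (stops, and Met for SDA) are excluded from both the
#' product and the length.
#'
#' @param weights Named numeric vector of per-codon weights (`NA` entries
#'   are skipped).
#' @param counts A `codon_counts` matrix.
#' @return Named numeric vector of gene scores.
#' @export
gene_geometric_score <- function(weights, counts) {
  weights <- weights[!is.na(weights)]
  if (any(weights <= 0)) stop("non-positive weights; replace zeros first")
  m <- unclass(counts)[, names(weights), drop = FALSE]
  lg <- rowSums(m)
  if (any(lg == 0)) {
    stop("gene(s) with no scoreable codons: ",
         paste(utils::head(rownames(m)[lg == 0], 5L), collapse = ", "))
  }
  exp(as.numeric(m %*% log(weights)) / lg) |> setNames(rownames(m))
}

#' Gene tAI scores
#'
#' @param weights A `tai_weights` object.
#' @param counts A `codon_counts` matrix.
#' @return Named numeric vector of per-gene tAI.
#' @export
gene_tai <- function(weights, counts) {
  gene_geometric_score(weights$w, counts)
}

#' Relative tAI weights (family-normalized supply)
#'
#' Each tAI weight divided by the maximum weight among the synonymous
#' codons of its amino acid, removing amino-acid composition effects; the
#' per-family maximum is 1. This is the codon supply entering the SDA.
#'
#' @param weights A `tai_weights` object.
#' @return Named numeric vector `Rw` over the 61 sense codons.
#' @export
relative_tai_weights <- function(weights) {
  ct <- codon_table()
  sense <- ct[!ct$is_stop, ]
  fam <- sense$amino_acid[match(names(weights$w), sense$codon)]
  setNames(.family_scale(weights$w, fam, max), names(weights$w))
}

#' Expression-weighted codon demand
#'
#' Codon usage at the transcriptome level: counts of each codon per gene,
#' weighted by the gene's mRNA abundance and summed over genes
#' (`CU_c = sum_j c_ij * mRNA_j`), then normalized within each amino-acid
#' family to the most demanded synonymous codon (`D_c = CU_c / max_fam CU`).
#'
#' @param counts A `codon_counts` matrix.
#' @param expression Named numeric vector of linear-scale mRNA abundances
#'   (gene ids matching `rownames(counts)`; the intersection is used).
#' @return List with `CU` and `D`, both named over the 61 sense codons,
#'   and `n_genes_used`.
#' @export
codon_demand <- function(counts, expression) {
  if (any(expression < 0, na.rm = TRUE)) stop("negative expression")
  common <- intersect(rownames(counts), names(expression))
  if (!length(common)) stop("no shared gene identifiers")
  if (length(common) < nrow(counts)) {
    message(nrow(counts) - length(common),
            " gene(s) without expression dropped from demand")
  }
  expr <- expression[common]
  if (all(expr == 0, na.rm = TRUE)) stop("all expression values are zero")
  m <- unclass(counts)[common, sense_codons(), drop = FALSE]
  CU <- setNames(as.numeric(crossprod(m, expr)), colnames(m))
  ct <- codon_table()
  fam <- ct$amino_acid[match(names(CU), ct$codon)]
  D <- setNames(.family_scale(CU, fam, max), names(CU))
  list(CU = CU, D = D, n_genes_used = length(common))
}

#' Supply-to-Demand Adaptation weights (SDAw)
#'
#' The per-codon ratio of family-normalized anticodon supply `S_c` (the
#' relative tAI weight) to family-normalized codon demand `D_c`, defined
#' for the 60 codons excluding methionine and stops. Codons whose family
#' demand is zero are flagged missing rather than infinite.
#'
#' @param supply Named numeric vector of relative tAI weights
#'   ([relative_tai_weights()]).
#' @param demand Result of [codon_demand()] (or a named `D` vector).
#' @return Named numeric vector `SDAw` over the 60 codons (`NA` where
#'   demand is missing), with attribute `missing` listing flagged codons.
#' @export
sda_weights <- function(supply, demand) {
  D <- if (is.list(demand)) demand$D else demand
  cods <- sda_codons()
  s <- supply[cods]; d <- D[cods]
  sdaw <- ifelse(!is.na(d) & d > 0, s / d, NA_real_)
  names(sdaw) <- cods
  attr(sdaw, "missing") <- cods[is.na(sdaw)]
  sdaw
}

#' Gene SDA scores
#'
#' Length-normalized geometric mean of SDAw over a gene's codons;
#' methionine and stop codons are skipped and excluded from the length.
#'
#' @param sdaw SDAw vector from [sda_weights()].
#' @param counts A `codon_counts` matrix.
#' @return Named numeric vector of per-gene SDA.
#' @export
gene_sda <- function(sdaw, counts) {
  gene_geometric_score(sdaw, counts)
}

#' Full translational-efficiency table for one sample
#'
#' Convenience wrapper chaining sqrt-normalized supply, tAI weights,
#' relative weights, demand and SDAw, plus per-gene tAI/RtAI/SDA scores.
#'
#' @param profile An `isoacceptor_profile` (cytosolic supply is taken from
#'   sqrt-RPM).
#' @param counts A `codon_counts` matrix for the CDS set.
#' @param expression Named numeric vector of mRNA abundances.
#' @param s Selective-constraint vector.
#' @return List with `weights` (data.frame codon, amino_acid, W, w, Rw,
#'   CU, D, SDAw) and `genes` (data.frame gene_id, l_g, tAI, RtAI, SDA).
#' @export
sda_pipeline <- function(profile, counts, expression,
                         s = default_s_vector()) {
  supply_in <- sqrt_normalize(profile)
  tw <- tai_weights(supply_in, s = s)
  Rw <- relative_tai_weights(tw)
  dem <- codon_demand(counts, expression)
  sdaw <- sda_weights(Rw, dem)
  ct <- codon_table()
  cods <- sense_codons()
  weights <- data.frame(
    codon = cods,
    amino_acid = ct$amino_acid[match(cods, ct$codon)],
    W = as.numeric(tw$W[cods]), w = as.numeric(tw$w[cods]),
    Rw = as.numeric(Rw[cods]),
    CU = as.numeric(dem$CU[cods]), D = as.numeric(dem$D[cods]),
    SDAw = as.numeric(sdaw[cods]),
    stringsAsFactors = FALSE
  )
  lg <- rowSums(unclass(counts)[, cods, drop = FALSE])
  genes <- data.frame(
    gene_id = rownames(counts), l_g = as.integer(lg),
    tAI = as.numeric(gene_tai(tw, counts)),
    RtAI = as.numeric(gene_geometric_score(Rw, counts)),
    SDA = as.numeric(gene_sda(sdaw, counts)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(weights = weights, genes = genes)
}
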