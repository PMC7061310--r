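#' Read alignment hits from SAM/BAM
#'
#' Loads all alignment records (secondary alignments included) into a hit
#' table. SAM text files are converted to BAM on the fly via
#' [Rsamtools::asBam()]. Mismatch counts are taken from the NM tag.
#'
#' @param path Path to a SAM or BAM file.
#' @return A data.frame with one row per alignment: `read_id`, `target`,
#'   `pos` (1-based leftmost), `cigar`, `nm`, `seq` (read bases, possibly
#'   `NA` on secondary records), `secondary`.
#' @export
read_sam_hits <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = FALSE)
  } else bam <- path
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    tag = "NM",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  x <- Rsamtools::scanBam(bam, param = p)[[1L]]
  seqs <- as.character(x$seq)
  seqs[seqs == ""] <- NA_character_
  data.frame(
    read_id = x$qname,
    target = as.character(x$rname),
    pos = x$pos,
    cigar = x$cigar,
    nm = if (is.null(x$tag$NM)) rep(NA_integer_, length(x$qname)) else x$tag$NM,
    seq = seqs,
    secondary = bitwAnd(x$flag, 256L) > 0L,
    stringsAsFactors = FALSE
  )
}

#' Filter out non-tRNA and pre-tRNA reads after the first mapping pass
#'
#' First-pass targets are the tRNA-masked chromosomes plus one pre-tRNA
#' contig per gene (named `pre_<gene_id>|<flank5>|<flank3>`). A read is
#' discarded when any of its hits lies on a masked chromosome (non-tRNA
#' read) or overlaps a pre-tRNA flank by at least one base (unprocessed
#' pre-tRNA read); flank overlap uses half-open intervals. Only reads whose
#' hits all fall within mature gene bodies are forwarded to the second
#' mapping pass.
#'
#' @param hits Hit table from [read_sam_hits()] for the first pass.
#' @param pretrna Pre-tRNA table from [build_pretrna_and_mask()]
#'   (`gene_id`, `seq`, `flank5`, `flank3`).
#' Reads with no first-pass hit at all are not excluded: mature-tRNA reads
#' spanning the splice junction or the CCA tail cannot map to the genome,
#' which is precisely why the second pass aligns against the mature
#' library.
#'
#' @param masked_chroms Character vector of masked chromosome names.
#' @return List with `excluded_ids` (reads to drop before the second
#'   pass), `retained_ids` (first-pass reads that survived), and the
#'   tallies `n_premature`, `n_genomic`.
#' @export
filter_premature <- function(hits, pretrna, masked_chroms) {
  pre_names <- paste0("pre_", pretrna$gene_id)
  target_gene <- sub("\\|.*$", "", hits$target)
  is_pre <- target_gene %in% pre_names
  is_masked <- hits$target %in% masked_chroms
  if (any(!is_pre & !is_masked)) {
    bad <- unique(hits$target[!is_pre & !is_masked])
    stop("unlabeled first-pass target(s): ", paste(bad, collapse = ", "))
  }
  idx <- match(sub("^pre_", "", target_gene), pretrna$gene_id)
  reflen <- Biostrings::width(Biostrings::BStringSet(pretrna$seq))[idx]
  alen <- GenomicAlignments::cigarWidthAlongReferenceSpace(hits$cigar)
  a0 <- hits$pos - 1L           # half-open [a0, a1) on the contig
  a1 <- a0 + alen
  f5 <- pretrna$flank5[idx]
  body_end <- reflen - pretrna$flank3[idx]
  in_flank <- is_pre & (a0 < f5 | a1 > body_end)
  genomic_reads <- unique(hits$read_id[is_masked])
  flank_reads <- setdiff(unique(hits$read_id[in_flank]), genomic_reads)
  excluded <- c(genomic_reads, flank_reads)
  list(excluded_ids = excluded,
       retained_ids = setdiff(unique(hits$read_id), excluded),
       n_premature = length(flank_reads),
       n_genomic = length(genomic_reads))
}

#' Assign reads to isoacceptors under the ambiguity rule
#'
#' For every read, the best-tier hits are those with the minimum mismatch
#' count (NM) among its alignments to the mature library. The read is
#' counted once for anticodon A when all best-tier hits land on clusters
#' carrying anticodon A -- reads ambiguous among isodecoders of one
#' isoacceptor are therefore kept, while reads whose best-tier hits span
#' two or more anticodons are discarded and tallied.
#'
#' @param hits Hit table from [read_sam_hits()] for the mature-library pass.
#' @param clusters A `trna_clusters` data.frame (targets are matched on
#'   `cluster_id`; FASTA-style `id|...` target names are accepted).
#' @return List with `counts` (named integer vector over anticodons),
#'   `n_assigned`, `n_ambiguous`, `n_unassigned` (reads with no resolvable
#'   hit).
#' @export
assign_reads <- function(hits, clusters) {
  if (!nrow(hits)) {
    return(list(counts = integer(0), n_assigned = 0L,
                n_ambiguous = 0L, n_unassigned = 0L))
  }
  cid <- sub("\\|.*$", "", hits$target)
  ac <- clusters$anticodon[match(cid, clusters$cluster_id)]
  if (anyNA(ac)) {
    stop("hit target(s) not in cluster table: ",
         paste(unique(cid[is.na(ac)]), collapse = ", "))
  }
  dt <- data.table::data.table(read_id = hits$read_id,
                               nm = ifelse(is.na(hits$nm), 0L, hits$nm),
                               anticodon = ac)
  per_read <- dt[, {
    best <- anticodon[nm == min(nm)]
    list(anticodon = if (length(unique(best)) == 1L) best[1L]
         else NA_character_)
  }, by = "read_id"]
  assigned <- per_read$anticodon[!is.na(per_read$anticodon)]
  counts <- table(assigned)
  counts <- setNames(as.integer(counts), names(counts))
  list(counts = counts,
       n_assigned = length(assigned),
       n_ambiguous = sum(is.na(per_read$anticodon)),
       n_unassigned = 0L)
}

#' Build an isoacceptor abundance profile
#'
#' Converts isoacceptor counts to reads-per-million. The RPM denominator is
#' the number of reads assigned at isoacceptor level, so profiles sum to
#' 10^6 and are comparable across sequencing depths.
#'
#' @param counts Named integer vector of reads per anticodon.
#' @param sample_id Sample label.
#' @param anticodons Anticodon universe for the profile rows (defaults to
#'   the anticodons present in `counts`); absent anticodons get zero.
#' @param n_ambiguous,n_premature Discard tallies carried into the profile.
#' @return Object of class `isoacceptor_profile`: a list with `sample_id`,
#'   `table` (data.frame: `anticodon`, `amino_acid`, `count`, `rpm`,
#'   `sqrt_rpm`), `total_assigned`, `discarded_ambiguous`,
#'   `discarded_premature`.
#' @export
isoacceptor_profile <- function(counts, sample_id = "sample",
                                anticodons = names(counts),
                                n_ambiguous = 0L, n_premature = 0L) {
  full <- setNames(integer(length(anticodons)), anticodons)
  full[names(counts)] <- counts
  total <- sum(full)
  rpm <- if (total > 0) full * 1e6 / total else full * 0
  tab <- data.frame(
    anticodon = anticodons,
    amino_acid = anticodon_aa(anticodons),
    count = as.integer(full),
    rpm = as.numeric(rpm),
    sqrt_rpm = sqrt(as.numeric(rpm)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(sample_id = sample_id, table = tab,
                 total_assigned = total,
                 discarded_ambiguous = n_ambiguous,
                 discarded_premature = n_premature),
            class = "isoacceptor_profile")
}

#' @export
print.isoacceptor_profile <- function(x, ...) {
  cat(sprintf("isoacceptor profile '%s': %d anticodons, %d assigned reads\n",
              x$sample_id, nrow(x$table), x$total_assigned))
  cat(sprintf("  discarded: %d ambiguous, %d premature/genomic\n",
              x$discarded_ambiguous, x$discarded_premature))
  invisible(x)
}

#' Square-root normalization of an isoacceptor profile
#'
#' @param profile An `isoacceptor_profile`.
#' @return Named numeric vector of sqrt(RPM) per anticodon.
#' @export
sqrt_normalize <- function(profile) {
  setNames(profile$table$sqrt_rpm, profile$table$anticodon)
}

#' Relative anticodon abundance (RAA)
#'
#' The contribution of each anticodon within the set of anticodons decoding
#' synonymous codons of one amino acid; family values sum to 1. Anticodons
#' whose cognate codon is a stop are excluded with a warning; families with
#' zero total abundance yield `NA` entries.
#'
#' @param profile An `isoacceptor_profile` (RPM view is used; RAA is
#'   invariant to the choice of linear abundance scale).
#' @return Data.frame `anticodon`, `amino_acid`, `raa`.
#' @export
relative_anticodon_abundance <- function(profile) {
  tab <- profile$table
  stopish <- tab$amino_acid == "Stop" | is.na(tab$amino_acid)
  if (any(stopish)) {
    warning("excluding stop-decoding anticodon(s): ",
            paste(tab$anticodon[stopish], collapse = ", "))
    tab <- tab[!stopish, , drop = FALSE]
  }
  fam_tot <- tapply(tab$rpm, tab$amino_acid, sum)
  denom <- as.numeric(fam_tot[tab$amino_acid])
  raa <- ifelse(denom > 0, tab$rpm / denom, NA_real_)
  data.frame(anticodon = tab$anticodon, amino_acid = tab$amino_acid,
             raa = raa, stringsAsFactors = FALSE, row.names = NULL)
}

#' Quantify one sample through the two-pass filtering contract
#'
#' Applies [filter_premature()] to the first-pass hits, restricts the
#' mature-library hits to retained reads, and assigns them to isoacceptors.
#'
#' @param first_hits First-pass hit table (masked genome + pre-tRNAs), or
#'   `NULL` to skip pre-filtering.
#' @param mature_hits Mature-library hit table.
#' @param clusters A `trna_clusters` data.frame.
#' @param pretrna,masked_chroms Passed to [filter_premature()].
#' @param sample_id Sample label.
#' @param anticodons Anticodon universe for the profile (default: all
#'   anticodons in `clusters`).
#' @return An `isoacceptor_profile`.
#' @export
quantify_sample <- function(first_hits = NULL, mature_hits, clusters,
                            pretrna = NULL, masked_chroms = character(0),
                            sample_id = "sample",
                            anticodons = sort(unique(clusters$anticodon))) {
  n_premature <- 0L
  if (!is.null(first_hits)) {
    filt <- filter_premature(first_hits, pretrna, masked_chroms)
    n_premature <- filt$n_premature + filt$n_genomic
    mature_hits <- mature_hits[!mature_hits$read_id %in% filt$excluded_ids, ,
                               drop = FALSE]
  }
  asn <- assign_reads(mature_hits, clusters)
  isoacceptor_profile(asn$counts, sample_id = sample_id,
                      anticodons = anticodons,
                      n_ambiguous = asn$n_ambiguous,
                      n_premature = n_premature)
}

#' Write an isoacceptor profile to TSV
#'
#' @param profile An `isoacceptor_profile`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  tab <- profile$table
  raa <- suppressWarnings(relative_anticodon_abundance(profile))
  tab$raa <- raa$raa[match(tab$anticodon, raa$anticodon)]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
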