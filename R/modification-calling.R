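#' Consensus tRNA structural template
#'
#' A canonical 76-nt mature tRNA (the classic cloverleaf reference
#' molecule, DNA alphabet, ending in the CCA tail) with one structural
#' label per column: positions are numbered "1".."76" with the anticodon
#' at 34-36, and each column carries a region annotation (acceptor stem,
#' D-arm, anticodon arm, V-region, T-arm, discriminator, CCA). Misread
#' positions of arbitrary tRNAs are projected onto these labels for
#' cross-tRNA comparability.
#'
#' @return List with `seq` (character), `labels` (character 76-vector) and
#'   `region` (character 76-vector).
#' @export
trna_model_template <- function() {
  seq <- paste0(
    "GCGGATTTAGCTCAGTTGGGAGAGCGCCAGACTGAAGATCTGGAGGTCCTGTGTTCGATC",
    "CACAGAATTCGCACCA"
  )
  stopifnot(nchar(seq) == 76L)
  region <- character(76L)
  region[1:7]   <- "acceptor-stem"
  region[8:9]   <- "linker"
  region[10:13] <- "D-stem"
  region[14:21] <- "D-loop"
  region[22:25] <- "D-stem"
  region[26]    <- "linker"
  region[27:31] <- "anticodon-stem"
  region[32:38] <- "anticodon-loop"
  region[39:43] <- "anticodon-stem"
  region[44:48] <- "V-region"
  region[49:53] <- "T-stem"
  region[54:60] <- "T-loop"
  region[61:65] <- "T-stem"
  region[66:72] <- "acceptor-stem"
  region[73]    <- "discriminator"
  region[74:76] <- "CCA"
  list(seq = seq, labels = as.character(1:76), region = region)
}

#' Restrict a hit table to uniquely mapped reads
#'
#' Keeps only reads with a single best-tier hit (minimum mismatch count),
#' returning that hit per read. Modification calling admits only these
#' reads so that multi-mapping cannot masquerade as misincorporation.
#'
#' @param hits Hit table from [read_sam_hits()].
#' @return Subset of `hits`, one row per uniquely mapped read, with the
#'   primary record's sequence attached.
#' @export
unique_hit_reads <- function(hits) {
  if (!nrow(hits)) return(hits)
  dt <- data.table::as.data.table(hits)
  nm <- NULL  # NSE guard
  dt[, nm := ifelse(is.na(nm), 0L, nm)]
  best <- dt[, .SD[nm == min(nm)], by = "read_id"]
  n_best <- best[, list(n = .N), by = "read_id"]
  uniq <- n_best$read_id[n_best$n == 1L]
  out <- as.data.frame(best[best$read_id %in% uniq, ])
  # secondary records may lack SEQ; restore it from the read's primary line
  miss <- is.na(out$seq)
  if (any(miss)) {
    prim <- hits[!hits$secondary & !is.na(hits$seq), ]
    out$seq[miss] <- prim$seq[match(out$read_id[miss], prim$read_id)]
  }
  out
}

#' Per-position base pileup over mature tRNA clusters
#'
#' Tallies read bases per reference position for each cluster from
#' uniquely mapped reads. Read sequences are laid onto the reference
#' through their CIGAR (insertions and clips removed, deletions as
#' `del`).
#'
#' @param hits Hit table of uniquely mapped reads ([unique_hit_reads()]).
#' @param clusters A `trna_clusters` data.frame.
#' @return Data.frame with one row per covered position: `cluster_id`,
#'   `position` (0-based offset in the mature sequence), `ref_base`,
#'   `depth`, `A`, `C`, `G`, `T`, `del`.
#' @export
pileup_clusters <- function(hits, clusters) {
  if (!nrow(hits)) {
    return(data.frame(cluster_id = character(0), position = integer(0),
                      ref_base = character(0), depth = integer(0),
                      A = integer(0), C = integer(0), G = integer(0),
                      T = integer(0), del = integer(0)))
  }
  cid <- sub("\\|.*$", "", hits$target)
  bad <- setdiff(unique(cid), clusters$cluster_id)
  if (length(bad)) stop("read(s) referencing unknown cluster: ",
                        paste(bad, collapse = ", "))
  out <- list()
  for (cl in unique(cid)) {
    sel <- hits[cid == cl, , drop = FALSE]
    refseq <- clusters$mature_seq[clusters$cluster_id == cl]
    reflen <- nchar(refseq)
    layered <- GenomicAlignments::sequenceLayer(
      Biostrings::DNAStringSet(sel$seq), sel$cigar,
      from = "query", to = "reference")
    cm <- Biostrings::consensusMatrix(layered, shift = sel$pos - 1L,
                                      width = reflen)
    bases <- c("A", "C", "G", "T", "-")
    cm <- cm[bases, , drop = FALSE]
    depth <- colSums(cm)
    covered <- which(depth > 0)
    if (!length(covered)) next
    out[[cl]] <- data.frame(
      cluster_id = cl, position = covered - 1L,
      ref_base = strsplit(refseq, "")[[1L]][covered],
      depth = as.integer(depth[covered]),
      A = as.integer(cm["A", covered]), C = as.integer(cm["C", covered]),
      G = as.integer(cm["G", covered]), T = as.integer(cm["T", covered]),
      del = as.integer(cm["-", covered]),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  if (!length(out)) {
    return(pileup_clusters(hits[0, ], clusters))
  }
  res <- do.call(rbind, out)
  res[order(res$cluster_id, res$position), , drop = FALSE]
}

#' Call candidate modification sites from misincorporation
#'
#' A transparent threshold caller: a site is emitted when its depth and
#' the fraction of non-reference calls both reach their floors. The
#' misincorporation fraction, not the genotype, is the discovery signal.
#'
#' @param pileup Pileup table from [pileup_clusters()].
#' @param min_depth Minimum read depth (default 20).
#' @param min_fraction Minimum non-reference fraction (default 0.1).
#' @return Data.frame ordered by (cluster, position): `cluster_id`,
#'   `position`, `ref_base`, `depth`, `alt_fraction`, `dominant_alt`.
#' @export
call_sites <- function(pileup, min_depth = 20L, min_fraction = 0.1) {
  stopifnot(min_depth >= 1L, min_fraction > 0, min_fraction <= 1)
  if (!nrow(pileup)) {
    return(data.frame(cluster_id = character(0), position = integer(0),
                      ref_base = character(0), depth = integer(0),
                      alt_fraction = numeric(0),
                      dominant_alt = character(0)))
  }
  bases <- c("A", "C", "G", "T", "del")
  cnt <- as.matrix(pileup[, bases])
  colnames(cnt) <- bases
  ref_idx <- match(pileup$ref_base, bases)
  ref_cnt <- cnt[cbind(seq_len(nrow(cnt)), ref_idx)]
  alt <- pileup$depth - ref_cnt
  frac <- ifelse(pileup$depth > 0, alt / pileup$depth, 0)
  keep <- pileup$depth >= min_depth & frac >= min_fraction
  alt_cnt <- cnt
  alt_cnt[cbind(seq_len(nrow(cnt)), ref_idx)] <- -1L
  dom <- bases[max.col(alt_cnt, ties.method = "first")]
  out <- data.frame(
    cluster_id = pileup$cluster_id, position = pileup$position,
    ref_base = pileup$ref_base, depth = pileup$depth,
    alt_fraction = frac, dominant_alt = dom,
    stringsAsFactors = FALSE, row.names = NULL
  )[keep, , drop = FALSE]
  out[order(out$cluster_id, out$position), , drop = FALSE]
}

#' Project mature-sequence offsets onto the consensus tRNA model
#'
#' Globally aligns a cluster sequence to the structural template and maps
#' each 0-based mature offset to the label of the template column it
#' aligns to. Offsets falling in insertions relative to the template are
#' labeled `"V-region"` when flanking the variable region, otherwise
#' `"i<left column>"`. Sequences aligning below the identity floor return
#' `"unmapped"` for all positions.
#'
#' @param cluster_seq Mature cluster sequence.
#' @param positions Integer vector of 0-based offsets.
#' @param template Template from [trna_model_template()].
#' @param min_identity Percent-identity floor for a trusted projection
#'   (default 40).
#' @return Character vector of model position labels.
#' @export
map_to_model <- function(cluster_seq, positions,
                         template = trna_model_template(),
                         min_identity = 40) {
  n <- nchar(cluster_seq)
  stopifnot(all(positions >= 0L), all(positions < n))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(cluster_seq),
    subject = Biostrings::DNAString(template$seq),
    type = "global", substitutionMatrix = mat,
    gapOpening = 3, gapExtension = 1)
  if (Biostrings::pid(aln, type = "PID1") < min_identity) {
    return(rep("unmapped", length(positions)))
  }
  pc <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1L]]
  sc <- strsplit(as.character(Biostrings::subject(aln)), "")[[1L]]
  proj <- character(n)
  p <- 0L; t <- 0L
  for (i in seq_along(pc)) {
    if (sc[i] != "-") t <- t + 1L
    if (pc[i] != "-") {
      p <- p + 1L
      proj[p] <- if (sc[i] != "-") {
        template$labels[t]
      } else if (t >= 1L && t < 76L &&
                 (template$region[t] == "V-region" ||
                  template$region[t + 1L] == "V-region")) {
        "V-region"
      } else {
        paste0("i", t)
      }
    }
  }
  proj[positions + 1L]
}

#' Call and model-map modification sites for a sample
#'
#' Orchestrates [unique_hit_reads()], [pileup_clusters()], [call_sites()]
#' and [map_to_model()].
#'
#' @param hits Hit table from [read_sam_hits()] (mature-library pass).
#' @param clusters A `trna_clusters` data.frame.
#' @param min_depth,min_fraction Caller thresholds.
#' @param template Structural template.
#' @return Data.frame of modification sites with a `model_position`
#'   column.
#' @export
call_modifications <- function(hits, clusters, min_depth = 20L,
                               min_fraction = 0.1,
                               template = trna_model_template()) {
  uh <- unique_hit_reads(hits)
  pu <- pileup_clusters(uh, clusters)
  sites <- call_sites(pu, min_depth = min_depth,
                      min_fraction = min_fraction)
  sites$model_position <- rep(NA_character_, nrow(sites))
  for (cl in unique(sites$cluster_id)) {
    sel <- sites$cluster_id == cl
    seq <- clusters$mature_seq[clusters$cluster_id == cl]
    sites$model_position[sel] <-
      map_to_model(seq, sites$position[sel], template = template)
  }
  sites
}
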