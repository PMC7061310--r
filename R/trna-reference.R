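#' Parse a tRNA gene annotation against a genome
#'
#' Reads tRNA gene coordinates from either tRNAscan-SE tabular output
#' (1-based inclusive coordinates, start > end on the minus strand) or a
#' BED12 file (0-based half-open; blocks are exons, gaps are introns) and
#' attaches the gene-oriented genomic sequence from the genome. Coordinates
#' are normalized to the internal convention: 0-based half-open on the plus
#' axis, with intron intervals expressed as gene-local, gene-oriented
#' offsets.
#'
#' @param annotation_file Path to a tRNAscan-SE tabular file or BED12 file.
#' @param genome A [Biostrings::DNAStringSet] or path to a genome FASTA.
#' @param dialect `"auto"` (default), `"trnascan"` or `"bed12"`.
#' @param mito_chroms Chromosome names treated as mitochondrial.
#' @return A data.frame of class `trna_genes` with one row per gene:
#'   `gene_id`, `chrom`, `start`, `end` (0-based half-open), `strand`,
#'   `amino_acid`, `anticodon`, `is_mito`, `genomic_seq` (gene-oriented),
#'   and a list-column `introns` of two-column matrices of gene-local
#'   half-open intervals.
#' @export
parse_trna_annotation <- function(annotation_file, genome,
                                  dialect = c("auto", "trnascan", "bed12"),
                                  mito_chroms = c("chrM", "MT", "chrMT")) {
  dialect <- match.arg(dialect)
  genome <- .as_dna_set(genome)
  lines <- readLines(annotation_file)
  lines <- lines[nzchar(trimws(lines))]
  if (dialect == "auto") dialect <- .detect_dialect(lines)
  rows <- switch(dialect,
    trnascan = .parse_trnascan(lines),
    bed12 = .parse_bed12(lines)
  )

  keep <- rep(TRUE, nrow(rows))
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    if (!r$chrom %in% names(genome)) {
      stop(sprintf("row %d (%s): chromosome '%s' not in genome",
                   r$row, r$gene_id, r$chrom))
    }
    if (r$end > length(genome[[r$chrom]]) || r$start < 0L ||
        r$end <= r$start) {
      stop(sprintf("row %d (%s): coordinates %d-%d outside chromosome '%s'",
                   r$row, r$gene_id, r$start, r$end, r$chrom))
    }
    ac <- toupper(r$anticodon)
    if (nchar(ac) != 3L || grepl("[^ACGT]", ac)) {
      warning(sprintf("row %d (%s): unknown anticodon '%s'; row rejected",
                      r$row, r$gene_id, r$anticodon))
      keep[i] <- FALSE
    }
  }
  rows <- rows[keep, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no valid tRNA gene rows parsed")

  rows$anticodon <- toupper(rows$anticodon)
  rows$is_mito <- rows$chrom %in% mito_chroms
  seqs <- character(nrow(rows))
  introns_local <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    s <- Biostrings::subseq(genome[[r$chrom]], r$start + 1L, r$end)
    if (r$strand == "-") s <- Biostrings::reverseComplement(s)
    seqs[i] <- as.character(s)
    iv <- rows$introns_genomic[[i]]  # 0-based half-open, plus axis
    if (is.null(iv) || nrow(iv) == 0L) {
      introns_local[[i]] <- matrix(integer(0), ncol = 2L)
    } else {
      if (r$strand == "+") {
        loc <- cbind(iv[, 1L] - r$start, iv[, 2L] - r$start)
      } else {
        loc <- cbind(r$end - iv[, 2L], r$end - iv[, 1L])
      }
      loc <- loc[order(loc[, 1L]), , drop = FALSE]
      if (any(loc[, 1L] < 0L) || any(loc[, 2L] > r$end - r$start))
        stop(sprintf("row %d (%s): intron outside gene span", r$row, r$gene_id))
      if (nrow(loc) > 1L && any(loc[-1L, 1L] < loc[-nrow(loc), 2L]))
        stop(sprintf("row %d (%s): overlapping introns", r$row, r$gene_id))
      introns_local[[i]] <- loc
    }
  }

  out <- data.frame(
    gene_id = rows$gene_id, chrom = rows$chrom,
    start = rows$start, end = rows$end, strand = rows$strand,
    amino_acid = rows$amino_acid, anticodon = rows$anticodon,
    is_mito = rows$is_mito, genomic_seq = seqs,
    stringsAsFactors = FALSE
  )
  out$introns <- introns_local
  class(out) <- c("trna_genes", "data.frame")
  out
}

.as_dna_set <- function(genome) {
  if (is.character(genome) && length(genome) == 1L) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  stopifnot(methods::is(genome, "DNAStringSet"))
  genome
}

.detect_dialect <- function(lines) {
  body <- lines[!grepl("^(Sequence|Name|--------)", lines)]
  f <- strsplit(body[1L], "\t")[[1L]]
  if (length(f) >= 12L && !is.na(suppressWarnings(as.integer(f[2L]))) &&
      grepl(",", f[11L])) "bed12" else "trnascan"
}

# tRNAscan-SE tabular: SeqName  tRNA#  Begin  End  Type  Anticodon
#   IntronBegin  IntronEnd  Score [...]; 1-based inclusive, Begin > End on
# the minus strand; intron 0 0 means none.
.parse_trnascan <- function(lines) {
  body <- lines[!grepl("^(Sequence|Name|--------)", lines)]
  recs <- lapply(seq_along(body), function(i) {
    f <- trimws(strsplit(body[i], "\t")[[1L]])
    if (length(f) < 8L) stop(sprintf("row %d: too few columns", i))
    b <- as.integer(f[3L]); e <- as.integer(f[4L])
    if (is.na(b) || is.na(e)) stop(sprintf("row %d: non-numeric coordinates", i))
    if (b == e) stop(sprintf("row %d: start == end", i))
    strand <- if (b < e) "+" else "-"
    start <- min(b, e) - 1L; end <- max(b, e)
    ib <- as.integer(f[7L]); ie <- as.integer(f[8L])
    iv <- if (!is.na(ib) && !is.na(ie) && ib != 0L && ie != 0L) {
      matrix(c(min(ib, ie) - 1L, max(ib, ie)), ncol = 2L)
    } else matrix(integer(0), ncol = 2L)
    aa <- f[5L]
    list(row = i, chrom = f[1L],
         gene_id = sprintf("%s.tRNA%s-%s%s", f[1L], f[2L], aa, toupper(f[6L])),
         start = start, end = end, strand = strand,
         amino_acid = aa, anticodon = f[6L], introns_genomic = iv)
  })
  .bind_annot(recs)
}

# BED12 with names like "tRNA-Pro-AGG-1-1" (amino acid and anticodon drawn
# from the name); blocks are exons so inter-block gaps are introns.
.parse_bed12 <- function(lines) {
  recs <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t")[[1L]]
    if (length(f) < 12L) stop(sprintf("row %d: BED12 needs 12 columns", i))
    start <- as.integer(f[2L]); end <- as.integer(f[3L])
    if (is.na(start) || is.na(end) || end <= start)
      stop(sprintf("row %d: bad BED coordinates", i))
    m <- regmatches(f[4L],
                    regexec("([A-Za-z]{3,4})-([ACGTacgt]{3})(-|$)",
                            f[4L]))[[1L]][1:3]
    if (length(m) != 3L || anyNA(m))
      stop(sprintf("row %d: cannot parse amino acid/anticodon from '%s'",
                   i, f[4L]))
    nblock <- as.integer(f[10L])
    sizes <- as.integer(strsplit(f[11L], ",")[[1L]])[seq_len(nblock)]
    starts <- as.integer(strsplit(f[12L], ",")[[1L]])[seq_len(nblock)]
    iv <- if (nblock > 1L) {
      cbind(start + starts[-nblock] + sizes[-nblock], start + starts[-1L])
    } else matrix(integer(0), ncol = 2L)
    list(row = i, chrom = f[1L], gene_id = f[4L],
         start = start, end = end, strand = f[6L],
         amino_acid = m[2L], anticodon = m[3L], introns_genomic = iv)
  })
  .bind_annot(recs)
}

.bind_annot <- function(recs) {
  out <- data.frame(
    row = vapply(recs, `[[`, 1L, "row"),
    chrom = vapply(recs, `[[`, "", "chrom"),
    gene_id = vapply(recs, `[[`, "", "gene_id"),
    start = vapply(recs, `[[`, 1L, "start"),
    end = vapply(recs, `[[`, 1L, "end"),
    strand = vapply(recs, `[[`, "", "strand"),
    amino_acid = vapply(recs, `[[`, "", "amino_acid"),
    anticodon = vapply(recs, `[[`, "", "anticodon"),
    stringsAsFactors = FALSE
  )
  out$introns_genomic <- lapply(recs, `[[`, "introns_genomic")
  out
}

#' Mature tRNA sequence of a gene
#'
#' Removes annotated introns from the gene-oriented sequence and appends the
#' post-transcriptional 3' CCA tail. CCA is always appended, also for genes
#' whose genomic sequence already ends in CCA (such genes are reported via
#' the `duplicate_cca` attribute of [build_mature_library()]).
#'
#' @param genomic_seq Gene-oriented nucleotide string.
#' @param introns Two-column matrix of gene-local half-open intron intervals.
#' @return Mature sequence ending in `"CCA"`.
#' @export
mature_sequence <- function(genomic_seq, introns) {
  n <- nchar(genomic_seq)
  keep <- rep(TRUE, n)
  if (!is.null(introns) && nrow(introns) > 0L) {
    for (j in seq_len(nrow(introns))) {
      keep[(introns[j, 1L] + 1L):introns[j, 2L]] <- FALSE
    }
  }
  exonic <- paste(strsplit(genomic_seq, "")[[1L]][keep], collapse = "")
  if (nchar(exonic) == 0L) stop("intron removal empties the gene sequence")
  paste0(exonic, "CCA")
}

#' Build the mature tRNA library by 100%-identity clustering
#'
#' Splices and CCA-tails every gene and collapses identical mature
#' sequences into clusters; reads ambiguous among the members of one
#' cluster are indistinguishable and are quantified at the cluster level.
#' Mitochondrial genes and the special decoders (SeC, Sup, Und, iMet) are
#' clustered but flagged `metrics_eligible = FALSE` so they stay out of the
#' cytosolic supply pool by default while remaining quantifiable.
#'
#' @param genes A `trna_genes` data.frame from [parse_trna_annotation()].
#' @return A data.frame of class `trna_clusters`: `cluster_id`,
#'   `mature_seq`, `anticodon`, `amino_acid`, `n_members`,
#'   `metrics_eligible`, and list-column `member_gene_ids`. Attribute
#'   `duplicate_cca` lists genes whose genomic sequence already ended in CCA.
#' @export
build_mature_library <- function(genes) {
  if (!nrow(genes)) stop("empty gene list")
  mats <- vapply(seq_len(nrow(genes)), function(i) {
    mature_sequence(genes$genomic_seq[i], genes$introns[[i]])
  }, "")
  dup_cca <- genes$gene_id[endsWith(
    substr(mats, 1L, nchar(mats) - 3L), "CCA")]
  key <- split(seq_len(nrow(genes)), mats)
  ord <- order(vapply(key, min, 1L))
  key <- key[ord]
  seqs <- names(key)
  anticodon <- vapply(key, function(ix) {
    acs <- unique(genes$anticodon[ix])
    if (length(acs) != 1L)
      stop("identical mature sequences with different anticodons: ",
           paste(acs, collapse = ","))
    acs
  }, "")
  amino <- vapply(key, function(ix) genes$amino_acid[ix][1L], "")
  eligible <- vapply(key, function(ix) {
    !any(genes$is_mito[ix]) && !amino_in_special(genes$amino_acid[ix][1L])
  }, TRUE)
  id_counter <- stats::ave(seq_along(anticodon),
                           paste(amino, anticodon), FUN = seq_along)
  out <- data.frame(
    cluster_id = sprintf("%s-%s-c%d", amino, anticodon, id_counter),
    mature_seq = seqs, anticodon = anticodon, amino_acid = amino,
    n_members = lengths(key), metrics_eligible = eligible,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$member_gene_ids <- lapply(key, function(ix) genes$gene_id[ix])
  attr(out, "duplicate_cca") <- dup_cca
  class(out) <- c("trna_clusters", "data.frame")
  out
}

amino_in_special <- function(aa) aa %in% c("SeC", "Sup", "Und")

#' Build pre-tRNA records and the tRNA-masked genome
#'
#' Pre-tRNAs are the unspliced gene sequences with genomic 5'/3' flanks
#' (gene orientation); reads matching the flanks indicate unprocessed
#' molecules and are filtered in the first mapping pass. The masked genome
#' replaces every annotated tRNA gene span by N so that first-pass hits on
#' it identify non-tRNA reads.
#'
#' @param genes A `trna_genes` data.frame.
#' @param genome A [Biostrings::DNAStringSet] or genome FASTA path.
#' @param flank_len Flank width in nucleotides (default 50).
#' @return List with `pretrna` (data.frame: `gene_id`, `seq`, `flank5`,
#'   `flank3`, `clipped`) and `masked_genome` (DNAStringSet).
#' @export
build_pretrna_and_mask <- function(genes, genome, flank_len = 50L) {
  stopifnot(flank_len >= 0L)
  genome <- .as_dna_set(genome)
  masked <- genome
  pre <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    chrlen <- length(genome[[g$chrom]])
    lo <- max(0L, g$start - flank_len)
    hi <- min(chrlen, g$end + flank_len)
    s <- Biostrings::subseq(genome[[g$chrom]], lo + 1L, hi)
    left <- g$start - lo; right <- hi - g$end
    if (g$strand == "-") {
      s <- Biostrings::reverseComplement(s)
      tmp <- left; left <- right; right <- tmp
    }
    pre[[i]] <- data.frame(
      gene_id = g$gene_id, seq = as.character(s),
      flank5 = left, flank3 = right,
      clipped = (left < flank_len || right < flank_len),
      stringsAsFactors = FALSE
    )
    Biostrings::subseq(masked[[g$chrom]], g$start + 1L, g$end) <-
      Biostrings::DNAString(paste(rep("N", g$end - g$start), collapse = ""))
  }
  pre <- do.call(rbind, pre)
  if (any(pre$clipped)) {
    message(sum(pre$clipped), " pre-tRNA flank(s) clipped at chromosome edges")
  }
  list(pretrna = pre, masked_genome = masked)
}

#' Write reference artifacts to a directory
#'
#' Writes the mature library FASTA (headers
#' `cluster_id|anticodon|amino_acid|n_members`), the cluster membership
#' TSV, the pre-tRNA FASTA (headers `pre_<gene_id>|flank5|flank3`) and the
#' masked genome FASTA.
#'
#' @param clusters A `trna_clusters` data.frame.
#' @param pretrna_mask Result of [build_pretrna_and_mask()] (or `NULL` to
#'   skip those artifacts).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference <- function(clusters, pretrna_mask = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lib <- Biostrings::DNAStringSet(clusters$mature_seq)
  names(lib) <- sprintf("%s|%s|%s|%d", clusters$cluster_id,
                        clusters$anticodon, clusters$amino_acid,
                        clusters$n_members)
  Biostrings::writeXStringSet(lib, file.path(dir, "mature.fa"))
  memb <- data.frame(
    cluster_id = rep(clusters$cluster_id, lengths(clusters$member_gene_ids)),
    gene_id = unlist(clusters$member_gene_ids),
    anticodon = rep(clusters$anticodon, lengths(clusters$member_gene_ids)),
    amino_acid = rep(clusters$amino_acid, lengths(clusters$member_gene_ids)),
    metrics_eligible = rep(clusters$metrics_eligible,
                           lengths(clusters$member_gene_ids)),
    stringsAsFactors = FALSE
  )
  write.table(memb, file.path(dir, "clusters.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(pretrna_mask)) {
    pt <- Biostrings::DNAStringSet(pretrna_mask$pretrna$seq)
    names(pt) <- sprintf("pre_%s|%d|%d", pretrna_mask$pretrna$gene_id,
                         pretrna_mask$pretrna$flank5,
                         pretrna_mask$pretrna$flank3)
    Biostrings::writeXStringSet(pt, file.path(dir, "pretrna.fa"))
    Biostrings::writeXStringSet(pretrna_mask$masked_genome,
                                file.path(dir, "masked_genome.fa"))
  }
  invisible(dir)
}

#' Read a mature library FASTA back into a cluster table
#'
#' Inverse of the FASTA side of [write_reference()]; membership is restored
#' from the companion `clusters.tsv` when present in the same directory.
#'
#' @param fasta Path to a mature library FASTA written by
#'   [write_reference()].
#' @return A `trna_clusters` data.frame.
#' @export
read_mature_library <- function(fasta) {
  lib <- Biostrings::readDNAStringSet(fasta)
  f <- strsplit(names(lib), "|", fixed = TRUE)
  out <- data.frame(
    cluster_id = vapply(f, `[`, "", 1L),
    mature_seq = as.character(lib),
    anticodon = vapply(f, `[`, "", 2L),
    amino_acid = vapply(f, `[`, "", 3L),
    n_members = as.integer(vapply(f, `[`, "", 4L)),
    metrics_eligible = TRUE,
    stringsAsFactors = FALSE, row.names = NULL
  )
  tsv <- file.path(dirname(fasta), "clusters.tsv")
  if (file.exists(tsv)) {
    memb <- read.table(tsv, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
    out$member_gene_ids <- lapply(out$cluster_id, function(cid) {
      memb$gene_id[memb$cluster_id == cid]
    })
    out$metrics_eligible <- memb$metrics_eligible[
      match(out$cluster_id, memb$cluster_id)]
  } else {
    out$member_gene_ids <- as.list(out$cluster_id)
  }
  class(out) <- c("trna_clusters", "data.frame")
  out
}
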