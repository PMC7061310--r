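# Shared fixtures, built in code.

# Independent reverse-complement oracle (no Biostrings).
rc_oracle <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

# Deterministic toy chromosome and a handcrafted tRNAscan-style annotation:
# a plus-strand intron-bearing gene and a minus-strand copy of its sequence.
toy_genome <- function() {
  set.seed(4242)
  left <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                collapse = "")
  gene_plus <- paste0(strrep("ACGT", 10), "GGGTTTCCC", strrep("TTAC", 8))
  mid <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
               collapse = "")
  gene_minus <- rc_oracle(gene_plus)
  right <- paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE),
                 collapse = "")
  chr <- paste0(left, gene_plus, mid, gene_minus, right)
  g <- Biostrings::DNAStringSet(chr)
  names(g) <- "chr1"
  attr(g, "gene_plus") <- gene_plus
  attr(g, "layout") <- list(
    p_start = 20L, p_end = 20L + nchar(gene_plus),          # 0-based half-open
    m_start = 20L + nchar(gene_plus) + 30L,
    m_end = 20L + 2L * nchar(gene_plus) + 30L,
    intron_local = c(40L, 49L)                               # the GGGTTTCCC block
  )
  g
}

toy_annotation <- function(genome = toy_genome()) {
  ly <- attr(genome, "layout")
  f <- tempfile(fileext = ".txt")
  writeLines(c(
    paste("chr1", 1, ly$p_start + 1L, ly$p_end, "Pro", "AGG",
          ly$p_start + ly$intron_local[1L] + 1L,
          ly$p_start + ly$intron_local[2L], "55.1", sep = "\t"),
    paste("chr1", 2, ly$m_end, ly$m_start + 1L, "Pro", "AGG",
          ly$m_end - ly$intron_local[1L],
          ly$m_end - ly$intron_local[2L] + 1L, "55.1", sep = "\t")
  ), f)
  f
}

# Simulated reference shared by read-level tests (memoised per session).
.ref_cache <- new.env(parent = emptyenv())
sim_ref_fixture <- function(seed = 42L) {
  key <- as.character(seed)
  if (!is.null(.ref_cache[[key]])) return(.ref_cache[[key]])
  cfg <- sim_config(seed = seed)
  ref <- simulate_reference(cfg)
  genes <- parse_trna_annotation(ref$annotation, ref$genome)
  clusters <- build_mature_library(genes)
  pm <- build_pretrna_and_mask(genes, ref$genome, flank_len = cfg$flank_len)
  out <- list(cfg = cfg, ref = ref, genes = genes, clusters = clusters,
              pretrna = pm$pretrna, masked = pm$masked_genome)
  .ref_cache[[key]] <- out
  out
}

# Dispersed truth abundances over the fixture's anticodons.
dispersed_truth <- function(clusters, seed = 5L) {
  acs <- sort(unique(clusters$anticodon))
  set.seed(seed)
  x <- exp(rnorm(length(acs)))
  setNames(x / sum(x), acs)
}

# Minimal hit-table constructor for quant/pileup unit tests.
hit_row <- function(read_id, target, pos = 1L, cigar = "10M", nm = 0L,
                    seq = NA_character_, secondary = FALSE) {
  data.frame(read_id = read_id, target = target, pos = pos, cigar = cigar,
             nm = nm, seq = seq, secondary = secondary,
             stringsAsFactors = FALSE)
}

# Brute-force Benjamini-Hochberg oracle.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  sorted <- p[o] * m / seq_len(m)
  q[o] <- rev(cummin(rev(sorted)))
  pmin(q, 1)
}

# Direct product-limit oracle: survival after each distinct event time.
km_oracle <- function(time, event) {
  ts <- sort(unique(time[event == 1L]))
  s <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    d <- sum(time == ts[i] & event == 1L)
    n <- sum(time >= ts[i])
    s <- s * (1 - d / n)
    out[i] <- s
  }
  data.frame(time = ts, surv = out)
}
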