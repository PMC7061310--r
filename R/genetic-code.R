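#' @import methods
#' @importFrom data.table data.table as.data.table := .N .SD
#' @importFrom stats median p.adjust wilcox.test binom.test lm pchisq
#'   complete.cases setNames rbinom rnorm rlnorm rexp runif quantile sd coef
#' @importFrom utils read.table write.table packageVersion
NULL

# Three-letter amino-acid names keyed by the one-letter code of the standard
# genetic code, plus the special labels used by tRNA gene annotations.
AA3 <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val", `*` = "Stop"
)

SPECIAL_AA <- c("SeC", "Sup", "Und", "iMet")

DNA_BASES <- c("A", "C", "G", "T")

#' Codon table of the standard genetic code
#'
#' Returns the 64 codons of NCBI genetic code table 1 with their encoded
#' amino acid and synonymous-family assignment. Six-fold degenerate amino
#' acids (Leu, Ser, Arg) are treated as single families.
#'
#' @return A data.frame with columns `codon`, `aa` (one-letter, `*` for
#'   stop), `amino_acid` (three-letter) and `is_stop`.
#' @export
codon_table <- function() {
  gc1 <- Biostrings::GENETIC_CODE
  codons <- names(gc1)
  data.frame(
    codon = codons,
    aa = unname(gc1),
    amino_acid = unname(AA3[gc1]),
    is_stop = unname(gc1 == "*"),
    stringsAsFactors = FALSE
  )
}

#' Sense codons
#'
#' @return Character vector of the 61 amino-acid-coding codons.
#' @export
sense_codons <- function() {
  ct <- codon_table()
  ct$codon[!ct$is_stop]
}

#' Codons scored by the Supply-to-Demand Adaptation
#'
#' The 60 codons entering SDAw: all sense codons except ATG (methionine has
#' no synonymous alternative and initiator/elongator tRNAs are not
#' distinguished by sequencing).
#'
#' @return Character vector of 60 codons.
#' @export
sda_codons <- function() {
  setdiff(sense_codons(), "ATG")
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Amino acid decoded by an anticodon
#'
#' The cognate codon of an anticodon is its reverse complement; the decoded
#' amino acid follows from the standard genetic code. Anticodons whose
#' cognate codon is a stop (TTA, CTA, TCA -- suppressors and
#' selenocysteine) decode no standard amino acid and return `"Stop"`.
#'
#' @param anticodon Character vector of 3-mer anticodons (DNA alphabet).
#' @return Three-letter amino-acid labels.
#' @export
anticodon_aa <- function(anticodon) {
  stopifnot(all(nchar(anticodon) == 3L))
  ct <- codon_table()
  ct$amino_acid[match(revcomp(anticodon), ct$codon)]
}

#' All 64 possible anticodons
#'
#' @return Character vector of the 64 anticodon 3-mers, named by codon box
#'   order (reverse complements of the 64 codons).
#' @export
all_anticodons <- function() {
  revcomp(codon_table()$codon)
}

# Family-wise normalization helper: x is a named-by-codon (or anticodon)
# vector, fam a parallel vector of family labels. Returns x / fun(family).
.family_scale <- function(x, fam, fun) {
  denom <- tapply(x, fam, fun)
  as.numeric(x) / as.numeric(denom[fam])
}
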