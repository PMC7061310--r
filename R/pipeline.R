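#' Run the end-to-end pipeline from a configuration
#'
#' Wires the stages buildref -> quant -> metrics -> callmods ->
#' diff/mlr/survival, each enabled by the presence of its block in the
#' YAML configuration, and writes every stage output plus a run manifest
#' (tool version, config hash, input checksums, per-stage record counts)
#' into the output directory. Inputs are validated before any stage runs;
#' no stage mutates its inputs, and reruns with identical inputs
#' reproduce identical non-timestamp bytes.
#'
#' Config schema (per-stage blocks; paths relative to the config file):
#' \preformatted{
#' buildref: {genome: g.fa, annot: trnas.txt, flank: 50}
#' quant:    {first_sam: first.sam, mature_sam: mature.sam, sample_id: s1}
#' metrics:  {cds: cds.fa, expr: expr.tsv}
#' callmods: {min_depth: 20, min_fraction: 0.1}
#' }
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#' @param out_dir Output directory.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- config
    config <- yaml::read_yaml(config)
  }
  base <- if (!is.null(cfg_path)) dirname(cfg_path) else "."
  rel <- function(p) if (file.exists(p)) p else file.path(base, p)

  # fail fast: resolve and check every referenced input before any stage
  inputs <- character(0)
  need <- function(block, key) {
    if (is.null(config[[block]][[key]]))
      stop(sprintf("config: %s.%s is required", block, key))
    p <- rel(config[[block]][[key]])
    if (!file.exists(p)) stop(sprintf("config: %s.%s: no such file: %s",
                                      block, key, p))
    inputs[[paste(block, key, sep = ".")]] <<- p
    p
  }
  if (!is.null(config$buildref)) { need("buildref", "genome"); need("buildref", "annot") }
  if (!is.null(config$quant)) need("quant", "mature_sam")
  if (!is.null(config$metrics)) { need("metrics", "cds"); need("metrics", "expr") }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()

  clusters <- NULL; pretrna_mask <- NULL; genes <- NULL
  if (!is.null(config$buildref)) {
    genome <- .as_dna_set(inputs[["buildref.genome"]])
    genes <- parse_trna_annotation(inputs[["buildref.annot"]], genome)
    clusters <- build_mature_library(genes)
    flank <- config$buildref$flank %||% 50L
    pretrna_mask <- build_pretrna_and_mask(genes, genome, flank_len = flank)
    write_reference(clusters, pretrna_mask, file.path(out_dir, "ref"))
    counts$buildref <- list(genes = nrow(genes), clusters = nrow(clusters))
  }

  profile <- NULL
  if (!is.null(config$quant)) {
    if (is.null(clusters)) stop("quant stage requires buildref")
    first_hits <- if (!is.null(config$quant$first_sam)) {
      read_sam_hits(need("quant", "first_sam"))
    } else NULL
    mature_hits <- read_sam_hits(inputs[["quant.mature_sam"]])
    profile <- quantify_sample(
      first_hits, mature_hits, clusters,
      pretrna = pretrna_mask$pretrna,
      masked_chroms = names(pretrna_mask$masked_genome),
      sample_id = config$quant$sample_id %||% "sample")
    write_profile(profile, file.path(out_dir, "isoacceptors.tsv"))
    counts$quant <- list(assigned = profile$total_assigned,
                         ambiguous = profile$discarded_ambiguous,
                         premature = profile$discarded_premature)
  }

  if (!is.null(config$metrics)) {
    if (is.null(profile)) stop("metrics stage requires quant")
    cc <- count_codons(inputs[["metrics.cds"]])
    expr_tab <- read.table(inputs[["metrics.expr"]], header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
    expr <- setNames(expr_tab[[2L]], expr_tab[[1L]])
    res <- sda_pipeline(profile, cc, expr)
    write.table(res$weights, file.path(out_dir, "weights.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(res$genes, file.path(out_dir, "gene_scores.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    counts$metrics <- list(codons = nrow(res$weights),
                           genes = nrow(res$genes))
  }

  if (!is.null(config$callmods)) {
    if (is.null(clusters)) stop("callmods stage requires buildref")
    mature_hits <- read_sam_hits(inputs[["quant.mature_sam"]])
    sites <- call_modifications(
      mature_hits, clusters,
      min_depth = config$callmods$min_depth %||% 20L,
      min_fraction = config$callmods$min_fraction %||% 0.1)
    write.table(sites, file.path(out_dir, "modifications.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    counts$callmods <- list(sites = nrow(sites))
  }

  manifest <- list(
    tool = "codonSDA",
    version = as.character(packageVersion("codonSDA")),
    config_hash = .hash_obj(config),
    inputs = as.list(vapply(inputs, .file_md5, "")),
    timestamp = format(Sys.time(), tz = "UTC"),
    stages = counts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.file_md5 <- function(p) unname(tools::md5sum(p))

.hash_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f)
  unname(tools::md5sum(f))
}
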