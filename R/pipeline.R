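## Orchestration: one configuration, stage selection, TSV outputs and a
## JSON summary report. Stage outputs are pure functions of
## (inputs, config); re-running a stage on unchanged inputs reproduces
## identical files.

#' Pipeline configuration
#'
#' Collects input paths and the analysis constants. All thresholds are
#' configuration, never literals inside the stage code: `min_orf_nt` (40),
#' `tcs_threshold` (0.5, strict), `psort_secreted_gt` (extracellular
#' score, strict >, 17), `psort_keep_ge` (localization score kept, >=,
#' 17), `junction_min_count` (2, i.e. singletons removed).
#'
#' @param annotation,genome,expression,junctions,domains,localization
#'   input paths (`junctions` may be a vector; unused stages may be
#'   `NULL`).
#' @param annotation_dialect `"gff3"` or `"gtf"`.
#' @param outdir output directory.
#' @param stages developmental stage axis for the expression table.
#' @param tf_domains character vector of transcription-factor domain
#'   accessions (or a path to a one-accession-per-line file).
#' @param min_orf_nt,tcs_threshold,psort_secreted_gt,psort_keep_ge,junction_min_count
#'   analysis constants.
#' @param seed integer seed recorded in the report.
#' @return validated config list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(annotation, genome,
                           expression = NULL, junctions = NULL,
                           domains = NULL, localization = NULL,
                           annotation_dialect = "gff3",
                           outdir = ".", stages = .DEFAULT_STAGES,
                           tf_domains = character(0),
                           min_orf_nt = 40L, tcs_threshold = 0.5,
                           psort_secreted_gt = 17, psort_keep_ge = 17,
                           junction_min_count = 2L, seed = 1L) {
  if (length(tf_domains) == 1L && file.exists(tf_domains))
    tf_domains <- readLines(tf_domains, warn = FALSE)
  cfg <- list(annotation = annotation, genome = genome,
              expression = expression, junctions = junctions,
              domains = domains, localization = localization,
              annotation_dialect = annotation_dialect,
              outdir = outdir, stages = stages, tf_domains = tf_domains,
              min_orf_nt = as.integer(min_orf_nt),
              tcs_threshold = tcs_threshold,
              psort_secreted_gt = psort_secreted_gt,
              psort_keep_ge = psort_keep_ge,
              junction_min_count = as.integer(junction_min_count),
              seed = as.integer(seed))
  if (cfg$min_orf_nt < 3L || cfg$tcs_threshold < 0 || cfg$tcs_threshold > 1)
    stop("config error: thresholds outside documented ranges")
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys match [pipelineConfig()] arguments.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(pipelineConfig, yaml::read_yaml(path))
}

#' Run the splicing analysis pipeline
#'
#' Runs, as inputs permit: annotation + genome loading, CDS assignment,
#' consensus-based event calling with three-level counts, junction
#' cluster events, time-course switch calls, and domain/localization
#' impact. Emits per-stage TSVs into `cfg$outdir` plus a JSON summary
#' (gene/transcript totals, transcripts-per-gene histogram, event counts
#' by type x region x level, TCS gene count, domain-change categories,
#' localization edges, config hash and seed).
#'
#' @param cfg a [pipelineConfig()].
#' @param stages character vector selecting stages to run (any of
#'   `"events"`, `"junctions"`, `"tcs"`, `"impact"`); annotation loading
#'   always runs.
#' @return the report, invisibly (also written as `report.json`).
#' @export
runPipeline <- function(cfg, stages = c("events", "junctions", "tcs", "impact")) {
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$outdir, f)
  need <- function(x, what, stage)
    if (is.null(x)) stop("missing mandatory input '", what,
                         "' for stage ", stage) else x

  genes <- readAnnotation(need(cfg$annotation, "annotation", "events"),
                          cfg$annotation_dialect)
  genome <- Biostrings::readDNAStringSet(need(cfg$genome, "genome", "events"))
  names(genome) <- sub("\\s.*$", "", names(genome))

  report <- list(
    tool = "consplice", version = as.character(utils::packageVersion("consplice")),
    seed = cfg$seed,
    config_hash = .configHash(cfg),
    genes_total = length(genes))

  ## CDS assignment (shared by events and impact)
  genes <- lapply(genes, function(g) {
    g@transcripts <- lapply(g@transcripts, function(tx)
      computeCdsUtrs(tx, genome, cfg$min_orf_nt)$tx)
    g
  })

  if ("events" %in% stages) {
    ev <- do.call(rbind, c(list(.emptyEvents()),
                           lapply(genes, callGeneEvents)))
    rownames(ev) <- NULL
    write.table(ev, out("events.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    counts <- lapply(c(event = "event", transcript = "transcript",
                       gene = "gene"),
                     function(l) countEvents(ev, l))
    countsLong <- do.call(rbind, lapply(names(counts), function(l)
      cbind(level = l, counts[[l]])))
    write.table(countsLong, out("event_counts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    txPerGene <- table(vapply(genes, function(g) length(g@transcripts),
                              integer(1)))
    asGenes <- unique(ev$gene_id)
    report$transcripts_total <- sum(vapply(genes, function(g)
      length(g@transcripts), integer(1)))
    report$genes_as <- length(asGenes)
    report$transcripts_per_gene <- as.list(setNames(as.integer(txPerGene),
                                                    names(txPerGene)))
    report$event_counts <- lapply(counts, function(cc)
      setNames(as.list(cc$total), cc$etype))
    report$event_counts_region <- lapply(counts, function(cc)
      list(coding = setNames(as.list(cc$coding), cc$etype),
           utr = setNames(as.list(cc$utr), cc$etype)))
    report$as_gene_ids <- sort(asGenes)
  }

  if ("junctions" %in% stages && !is.null(cfg$junctions)) {
    jn <- loadJunctions(cfg$junctions)
    jn <- clusterJunctions(jn)
    jev <- classifyJunctionEvents(jn, genes)
    write.table(jev, out("junction_events.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    report$junctions_kept <- nrow(jn)
    report$junction_events <- list(
      ASS = sum(jev$etype == "ASS"), ES = sum(jev$etype == "ES"))
    if (nrow(jev))
      report$junction_event_regions <- as.list(table(jev$region))
  }

  if ("tcs" %in% stages && !is.null(cfg$expression)) {
    prof <- readExpressionProfiles(cfg$expression, cfg$stages)
    tcs <- callTcs(prof, cfg$tcs_threshold, cfg$stages)
    write.table(tcs, out("tcs.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    dom <- stageDominanceCounts(prof, 0, cfg$stages)
    write.table(data.frame(stage = names(dom), count = as.integer(dom)),
                out("stage_dominance.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    report$tcs_genes <- length(unique(tcs$gene_id[tcs$is_tcs]))
    report$stage_dominance <- as.list(setNames(as.integer(dom), names(dom)))
  }

  if ("impact" %in% stages && !is.null(cfg$domains)) {
    hits <- read.delim(cfg$domains, stringsAsFactors = FALSE)
    byGene <- split(hits, hits$gene_id)
    txByGene <- setNames(lapply(genes, transcripts),
                         vapply(genes, geneId, character(1)))
    cats <- vapply(names(byGene), function(gId) {
      txs <- txByGene[[gId]]
      located <- reindexDomains(byGene[[gId]], txs)
      sets <- lapply(vapply(txs, txId, character(1)), function(id)
        located$located_id[located$transcript_id == id])
      classifyDomainChange(sets)
    }, character(1))
    write.table(data.frame(gene_id = names(cats), category = cats),
                out("domain_change.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    report$domain_change <- as.list(table(cats))
  }

  if ("impact" %in% stages && !is.null(cfg$localization)) {
    loc <- read.delim(cfg$localization, stringsAsFactors = FALSE)
    edges <- list()
    for (gId in unique(loc$gene_id)) {
      lg <- loc[loc$gene_id == gId, , drop = FALSE]
      perTx <- vapply(unique(lg$transcript_id), function(id) {
        sc <- setNames(lg$score[lg$transcript_id == id],
                       lg$location[lg$transcript_id == id])
        filterLocalization(sc, cfg$psort_keep_ge)
      }, character(1))
      cl <- classifyLocalizationChange(perTx)
      if (cl$status == "changed")
        edges[[length(edges) + 1L]] <- cbind(gene_id = gId, cl$edges)
    }
    edgeDf <- if (length(edges)) do.call(rbind, edges) else
      data.frame(gene_id = character(0), loc1 = character(0),
                 loc2 = character(0))
    write.table(edgeDf, out("localization_edges.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    report$localization_change_genes <- length(unique(edgeDf$gene_id))
    if (nrow(edgeDf)) {
      key <- paste(edgeDf$loc1, edgeDf$loc2, sep = "--")
      report$localization_edges <- as.list(table(key))
    }
  }

  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(report)
}

.configHash <- function(cfg) {
  cfg$outdir <- NULL   # the hash identifies the analysis, not its destination
  flat <- paste(names(unlist(cfg)), unlist(cfg), sep = "=", collapse = ";")
  tf <- tempfile(); writeLines(flat, tf); on.exit(unlink(tf))
  unname(tools::md5sum(tf))
}
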