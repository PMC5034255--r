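## Time-course switching (TCS): a gene whose alternative transcript
## overtakes its primary (highest-mean) transcript in expression at some
## developmental stage. The score is the dominance range of the relative
## expression r_t = alt/(alt + primary): identical-shape profiles score 0,
## a complete flip scores 1, and genes scoring strictly above the
## threshold (default 0.5) are called switches.

.DEFAULT_STAGES <- c("vegetative", "vegetative_induced", "aggregates",
                     "primordia", "mushroom")

#' Read per-transcript expression profiles
#'
#' @param path TSV with columns `transcript_id`, `gene_id`, then one
#'   numeric column per ordered developmental stage.
#' @param stages stage column names, in developmental order; defaults to
#'   the five-stage axis (vegetative, vegetative-induced, aggregates,
#'   primordia, mushroom).
#' @return data.frame of profiles (one row per transcript).
#' @export
readExpressionProfiles <- function(path, stages = .DEFAULT_STAGES) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("transcript_id", "gene_id", stages)
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("expression table missing column(s): ", paste(missing, collapse = ", "))
  if (any(as.matrix(df[stages]) < 0))
    stop("expression values must be nonnegative")
  df[need]
}

#' Primary transcript of a gene
#'
#' The transcript with the highest mean expression across stages; ties
#' break to the lexicographically smallest transcript id.
#'
#' @param profiles data.frame of one gene's profiles (columns
#'   `transcript_id` plus `stages`).
#' @param stages stage column names.
#' @return the primary transcript id.
#' @export
primaryTranscript <- function(profiles, stages = .DEFAULT_STAGES) {
  if (nrow(profiles) == 0L) stop("no expression profiles for gene")
  m <- rowMeans(as.matrix(profiles[stages]))
  ord <- order(-m, profiles$transcript_id)
  profiles$transcript_id[ord[1L]]
}

#' Time-course switching score of an alternative vs the primary profile
#'
#' Computes `r_t = alt_t / (alt_t + primary_t)` per stage (`r_t = 0.5`
#' when both are zero, keeping the profile length stable) and returns
#' `max(r) - min(r)`, in `[0, 1]`. Shape-identical profiles (one a
#' positive multiple of the other) give 0; a complete dominance flip
#' gives values near 1.
#'
#' @param primary,alt nonnegative numeric vectors over the same ordered
#'   stages (length >= 2).
#' @return score in `[0, 1]`.
#' @export
tcsScore <- function(primary, alt) {
  if (length(primary) != length(alt))
    stop("profile length mismatch: ", length(primary), " vs ", length(alt))
  if (length(primary) < 2L) stop("need at least two stages")
  tot <- primary + alt
  r <- ifelse(tot == 0, 0.5, alt / ifelse(tot == 0, 1, tot))
  max(r) - min(r)
}

#' Call time-course switching genes
#'
#' Scores every alternative transcript of every multi-transcript gene
#' against the gene's primary transcript. A gene is a switch if any
#' alternative scores strictly above `threshold`.
#'
#' @param profiles data.frame as from [readExpressionProfiles()].
#' @param threshold switching threshold (default 0.5, strict `>`).
#' @param stages stage column names.
#' @return data.frame with one row per (gene, alternative): `gene_id`,
#'   `primary_id`, `alt_id`, `score`, `is_tcs`, `dominance_stages`
#'   (comma-separated stages where the alternative exceeds the primary).
#' @export
callTcs <- function(profiles, threshold = 0.5, stages = .DEFAULT_STAGES) {
  out <- list()
  for (g in unique(profiles$gene_id)) {
    gp <- profiles[profiles$gene_id == g, , drop = FALSE]
    if (nrow(gp) < 2L) next
    pid <- primaryTranscript(gp, stages)
    pvec <- as.numeric(gp[gp$transcript_id == pid, stages])
    for (aid in setdiff(gp$transcript_id, pid)) {
      avec <- as.numeric(gp[gp$transcript_id == aid, stages])
      sc <- tcsScore(pvec, avec)
      dom <- stages[avec > pvec]
      out <- c(out, list(data.frame(
        gene_id = g, primary_id = pid, alt_id = aid, score = sc,
        is_tcs = sc > threshold,
        dominance_stages = paste(dom, collapse = ","),
        stringsAsFactors = FALSE)))
    }
  }
  if (length(out) == 0L)
    return(data.frame(gene_id = character(0), primary_id = character(0),
                      alt_id = character(0), score = numeric(0),
                      is_tcs = logical(0), dominance_stages = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-stage counts of dominant alternative transcripts
#'
#' For each stage, counts alternative transcripts that are more abundant
#' than their gene's primary transcript at that stage and exceed the
#' expression threshold there. Counts are monotone non-increasing in the
#' threshold.
#'
#' @param profiles data.frame as from [readExpressionProfiles()].
#' @param expressionThreshold minimum abundance for an alternative to be
#'   counted at a stage.
#' @param stages stage column names.
#' @return named integer vector over stages.
#' @export
stageDominanceCounts <- function(profiles, expressionThreshold = 0,
                                 stages = .DEFAULT_STAGES) {
  counts <- setNames(integer(length(stages)), stages)
  for (g in unique(profiles$gene_id)) {
    gp <- profiles[profiles$gene_id == g, , drop = FALSE]
    if (nrow(gp) < 2L) next
    pid <- primaryTranscript(gp, stages)
    pvec <- as.numeric(gp[gp$transcript_id == pid, stages])
    for (aid in setdiff(gp$transcript_id, pid)) {
      avec <- as.numeric(gp[gp$transcript_id == aid, stages])
      hit <- avec > pvec & avec > expressionThreshold
      counts <- counts + as.integer(hit)
    }
  }
  counts
}
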