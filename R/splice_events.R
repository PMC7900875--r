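#' Build a merged-CDS reference for an orthogroup
#'
#' Operationalises the "merge of high-quality CDSs": CDSs are incorporated
#' progressively (longest first) by global pairwise alignment against the
#' growing reference; reference-gap columns contribute the incoming CDS
#' segment, so the final reference carries every segment present in any
#' CDS exactly once. If an incoming CDS conflicts with the reference
#' (matched-column identity below \code{consistency_floor}), the merge
#' falls back to the longest CDS with a warning.
#'
#' @param cdss named character vector of CDS sequences (>= 1).
#' @param consistency_floor identity required over matched columns for a
#'   CDS to be merged (default 0.9).
#' @return object of class \code{merged_reference}: list with
#'   \code{sequence}, \code{length}, \code{n_merged}.
#' @export
build_merged_reference <- function(cdss, consistency_floor = 0.9) {
  if (!length(cdss)) .stopf("need at least one CDS")
  cdss <- cdss[order(nchar(cdss), decreasing = TRUE)]
  ref <- toupper(cdss[[1]])
  n_merged <- 1L
  if (length(cdss) > 1) {
    for (s in cdss[-1]) {
      s <- toupper(s)
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(s), Biostrings::DNAString(ref),
        type = "global", substitutionMatrix = .nuc_matrix(),
        gapOpening = 8, gapExtension = 0.5)
      gp <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
      gs <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
      both <- gp != "-" & gs != "-"
      ident <- if (any(both)) mean(gp[both] == gs[both]) else 0
      if (ident < consistency_floor) {
        warning("inconsistent CDS skipped during merge; reference kept")
        next
      }
      merged <- ifelse(gs != "-", gs, gp)
      ref <- paste0(merged, collapse = "")
      n_merged <- n_merged + 1L
    }
  }
  structure(list(sequence = ref, length = nchar(ref), n_merged = n_merged),
            class = "merged_reference")
}

#' Detect alternative-splicing events as large indels against the merged
#' reference
#'
#' Aligns the isoform semi-globally (terminal gaps free, so partial
#' coverage is not an event) with affine gap costs, fuses internal gap runs
#' separated by at most \code{fuse_within} aligned bases (guarding against
#' alignment jitter splitting one biological event), and reports every
#' fused run strictly longer than \code{min_len}: isoform-side gaps are
#' deletions, reference-side gaps insertions.
#'
#' @param isoform isoform sequence (character).
#' @param ref a [build_merged_reference()] result (or list with
#'   \code{sequence}).
#' @param min_len minimum event length, strict (default 51 bp: a 52-bp gap
#'   is an event, a 51-bp gap is not).
#' @param fuse_within fuse gap runs separated by <= this many aligned
#'   bases (default 2; 0 disables fusion).
#' @param identity_floor minimum identity over matched columns; below it
#'   the isoform is skipped (empty result, attribute
#'   \code{"skipped" = TRUE}).
#' @return data frame of class \code{as_events}: \code{kind}
#'   (\code{deletion}/\code{insertion}), \code{ref_start} (1-based
#'   reference coordinate of the event start; for insertions, the
#'   reference position after which the insertion occurs), \code{length_bp}.
#' @export
detect_as_events <- function(isoform, ref, min_len = 51L, fuse_within = 2L,
                             identity_floor = 0.7) {
  refseq <- if (is.list(ref)) ref$sequence else ref
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(isoform)), Biostrings::DNAString(refseq),
    type = "overlap", substitutionMatrix = .nuc_matrix(),
    gapOpening = 8, gapExtension = 0.5)
  gp <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  gs <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  empty <- data.frame(kind = character(0), ref_start = integer(0),
                      length_bp = integer(0), stringsAsFactors = FALSE)
  class(empty) <- c("as_events", "data.frame")
  both <- gp != "-" & gs != "-"
  ident <- if (any(both)) mean(gp[both] == gs[both]) else 0
  if (ident < identity_floor) {
    attr(empty, "skipped") <- TRUE
    return(empty)
  }
  # state per alignment column: 0 match-ish, 1 isoform gap (deletion),
  # 2 reference gap (insertion); track reference coordinate
  state <- ifelse(gp == "-", 1L, ifelse(gs == "-", 2L, 0L))
  refpos <- cumsum(gs != "-") + (Biostrings::start(Biostrings::subject(pa)) - 1L)
  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  gaps <- which(runs$values != 0L)
  if (!length(gaps)) return(empty)
  # fuse same-kind runs separated by short aligned stretches
  fused <- list()
  cur <- NULL
  for (gi in gaps) {
    g <- list(kind = runs$values[gi], start = starts[gi], end = ends[gi])
    if (!is.null(cur) && cur$kind == g$kind) {
      sep <- g$start - cur$end - 1L
      inter <- if (sep > 0) sum(state[(cur$end + 1L):(g$start - 1L)] == 0L) else 0L
      if (sep >= 0 && inter <= fuse_within && sep <= fuse_within) {
        cur$end <- g$end
        next
      }
    }
    if (!is.null(cur)) fused[[length(fused) + 1L]] <- cur
    cur <- g
  }
  fused[[length(fused) + 1L]] <- cur
  rows <- lapply(fused, function(g) {
    len <- sum(state[g$start:g$end] == g$kind)
    if (len <= min_len) return(NULL)
    data.frame(kind = if (g$kind == 1L) "deletion" else "insertion",
               ref_start = if (g$kind == 1L) refpos[g$start] else refpos[g$start],
               length_bp = len, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(rows)) do.call(rbind, rows) else empty
  class(out) <- c("as_events", "data.frame")
  out
}

#' Call AS events for a set of isoforms grouped by orthogroup
#'
#' Builds one merged reference per orthogroup from its member isoforms and
#' detects events for each isoform against it.
#'
#' @param isoforms named character vector of isoform sequences.
#' @param og_of named character vector mapping isoform id to orthogroup.
#' @param ... passed to [detect_as_events()].
#' @return data frame: \code{isoform_id}, \code{og}, \code{kind},
#'   \code{ref_start}, \code{length_bp}.
#' @export
call_as_events <- function(isoforms, og_of, ...) {
  rows <- list()
  for (og in unique(stats::na.omit(og_of))) {
    ids <- names(og_of)[!is.na(og_of) & og_of == og]
    ref <- build_merged_reference(isoforms[ids])
    for (id in ids) {
      ev <- detect_as_events(isoforms[[id]], ref, ...)
      if (nrow(ev)) {
        ev$isoform_id <- id
        ev$og <- og
        rows[[length(rows) + 1L]] <- ev
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(isoform_id = character(0), og = character(0),
                      kind = character(0), ref_start = integer(0),
                      length_bp = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[, c("isoform_id", "og", "kind", "ref_start", "length_bp")]
}

#' Tabulate AS events per sample and subgenome
#'
#' Joins events to subgenome calls; events on recombinant or unassigned
#' isoforms are excluded (counted in the \code{"excluded"} attribute). The
#' orthogroup share is reported to 2 decimals, as OGs with at least one
#' event over all identified OGs of the sample.
#'
#' @param events event table from [call_as_events()].
#' @param assignments an \code{isoform_assignments} data frame covering the
#'   events' isoforms.
#' @return data frame with one row per sample: per-subgenome isoform and
#'   event counts, total events, OGs with AS and their percentage.
#' @export
tabulate_as <- function(events, assignments) {
  amap <- setNames(assignments$call, assignments$isoform_id)
  smap <- setNames(assignments$sample, assignments$isoform_id)
  ev <- events
  ev$call <- amap[ev$isoform_id]
  ev$sample <- smap[ev$isoform_id]
  excluded <- sum(!(ev$call %in% c("M", "P")))
  ev <- ev[ev$call %in% c("M", "P"), , drop = FALSE]
  samples <- sort(unique(assignments$sample))
  rows <- lapply(samples, function(s) {
    a_s <- assignments[assignments$sample == s, ]
    e_s <- ev[!is.na(ev$sample) & ev$sample == s, ]
    identified_ogs <- length(unique(a_s$og[a_s$call %in% c("M", "P") &
                                             !is.na(a_s$og)]))
    n_iso <- function(sub) length(unique(e_s$isoform_id[e_s$call == sub]))
    n_ev <- function(sub) sum(e_s$call == sub)
    ogs_as <- length(unique(e_s$og))
    data.frame(sample = s,
               iso_M = n_iso("M"), events_M = n_ev("M"),
               iso_P = n_iso("P"), events_P = n_ev("P"),
               events_total = nrow(e_s), ogs_with_as = ogs_as,
               identified_ogs = identified_ogs,
               og_pct = round_half_up(
                 if (identified_ogs > 0) 100 * ogs_as / identified_ogs else 0, 2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- excluded
  out
}
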