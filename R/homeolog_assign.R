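#' Parental group definition
#'
#' Names the diploid taxa representing the maternal and paternal sides of
#' the allopolyploid. Defaults follow the Ephedra system: maternal
#' \emph{E. przewalskii} (\code{pr}) and \emph{E. regeliana} (\code{re});
#' paternal \emph{E. equisetina} (\code{eq}), \emph{E. minuta} (\code{mi})
#' and \emph{E. monosperma} (\code{mo}).
#'
#' @param maternal,paternal disjoint, non-empty character vectors of taxon
#'   labels as they appear in the orthogroup alignments.
#' @return object of class \code{parental_groups}.
#' @export
parental_groups <- function(maternal = c("pr", "re"),
                            paternal = c("eq", "mi", "mo")) {
  if (!length(maternal) || !length(paternal))
    .stopf("both parental groups must be non-empty")
  if (length(intersect(maternal, paternal)))
    .stopf("parental groups must be disjoint")
  structure(list(maternal = maternal, paternal = paternal),
            class = "parental_groups")
}

#' Assignment thresholds for diagnostic-site classification
#'
#' @param min_sites minimum diagnostic sites of the called parent required
#'   for a subgenome call (default 4, reflecting low coding-sequence
#'   variation).
#' @param hi,lo M-site proportion cutoffs: strictly above \code{hi} calls
#'   subgenome M, strictly below \code{lo} calls subgenome P; anything in
#'   between (ties included) is a recombinant.
#' @return object of class \code{assignment_thresholds}.
#' @export
assignment_thresholds <- function(min_sites = 4L, hi = 0.8, lo = 0.2) {
  if (!(.is_prob(hi) && .is_prob(lo) && lo < hi))
    .stopf("need 0 <= lo < hi <= 1")
  if (!.is_count(min_sites)) .stopf("min_sites must be a positive count")
  structure(list(min_sites = as.integer(min_sites), hi = hi, lo = lo),
            class = "assignment_thresholds")
}

# Alignment (named character vector or DNAStringSet) -> character matrix,
# rows = taxa, columns = alignment columns.
.aln_matrix <- function(og_alignment) {
  if (inherits(og_alignment, "DNAStringSet"))
    og_alignment <- setNames(as.character(og_alignment), names(og_alignment))
  lens <- nchar(og_alignment)
  if (length(unique(lens)) != 1) .stopf("alignment sequences differ in length")
  m <- do.call(rbind, strsplit(toupper(og_alignment), ""))
  rownames(m) <- names(og_alignment)
  m
}

#' Find parent-diagnostic alignment columns
#'
#' A column is diagnostic when every maternal taxon carries one identical
#' unambiguous base, every paternal taxon carries another identical
#' unambiguous base, and the two bases differ. Gaps and IUPAC ambiguity
#' codes in any diploid taxon disqualify the column.
#'
#' @param og_alignment named character vector (or \code{DNAStringSet}) of
#'   equal-length aligned sequences containing all taxa of both groups.
#' @param groups a [parental_groups()].
#' @return data frame of class \code{diagnostic_sites}: \code{column}
#'   (1-based alignment column), \code{m_allele}, \code{p_allele}.
#' @export
find_diagnostic_sites <- function(og_alignment, groups = parental_groups()) {
  m <- .aln_matrix(og_alignment)
  missing <- setdiff(c(groups$maternal, groups$paternal), rownames(m))
  if (length(missing))
    .stopf("alignment lacks taxa: %s", paste(missing, collapse = ", "))
  mm <- m[groups$maternal, , drop = FALSE]
  pm <- m[groups$paternal, , drop = FALSE]
  m_fixed <- apply(mm, 2, function(col) if (length(unique(col)) == 1) col[1] else NA)
  p_fixed <- apply(pm, 2, function(col) if (length(unique(col)) == 1) col[1] else NA)
  ok <- !is.na(m_fixed) & !is.na(p_fixed) &
    m_fixed %in% .BASES & p_fixed %in% .BASES & m_fixed != p_fixed
  out <- data.frame(column = which(ok), m_allele = m_fixed[ok],
                    p_allele = p_fixed[ok], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("diagnostic_sites", "data.frame")
  out
}

#' Majority-rule consensus of an orthogroup alignment
#'
#' Ties broken by alphabetical base order; gap-majority columns are kept as
#' the most frequent base among non-gap characters so the consensus stays
#' gapless and column indices remain alignment indices.
#'
#' @param og_alignment named character vector or DNAStringSet.
#' @return single character string.
#' @export
og_consensus <- function(og_alignment) {
  m <- .aln_matrix(og_alignment)
  cons <- apply(m, 2, function(col) {
    col <- col[col %in% .BASES]
    if (!length(col)) return("N")
    tab <- sort(table(col), decreasing = TRUE)
    names(tab)[1]
  })
  paste0(cons, collapse = "")
}

#' Score a polyploid isoform at the diagnostic columns of its orthogroup
#'
#' Aligns the isoform semi-globally (free end gaps) against the orthogroup
#' consensus with match 2 / mismatch -3 / gap open 5 / gap extend 2, and
#' reads off the isoform base at each diagnostic column covered by the
#' aligned span.
#'
#' @param isoform_seq isoform sequence (character).
#' @param og_reference orthogroup consensus sequence (character), in
#'   alignment coordinates (gapless).
#' @param sites a \code{diagnostic_sites} data frame for the orthogroup.
#' @param min_length minimum isoform length scored (full-length read
#'   definition; default 300 bp).
#' @param identity_floor minimum alignment identity; below it the isoform
#'   is reported unmatched.
#' @return list with \code{matched} (logical), \code{identity}, and
#'   \code{site_base}: character vector over \code{sites$column} giving the
#'   isoform base, or \code{NA} where the column is uncovered or gapped.
#' @export
align_isoform_to_og <- function(isoform_seq, og_reference, sites,
                                min_length = 300L, identity_floor = 0.7) {
  if (nchar(isoform_seq) < min_length)
    return(list(matched = FALSE, identity = NA_real_,
                site_base = rep(NA_character_, nrow(sites))))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(isoform_seq), Biostrings::DNAString(og_reference),
    type = "overlap", substitutionMatrix = .nuc_matrix(),
    gapOpening = 5, gapExtension = 2)
  .score_alignment(pa, sites, identity_floor)
}

# Shared extraction: map subject (reference) positions to pattern bases.
.score_alignment <- function(pa, sites, identity_floor) {
  aln_len <- nchar(as.character(Biostrings::alignedPattern(pa)))
  identity <- if (aln_len > 0) Biostrings::nmatch(pa) / aln_len else 0
  if (is.na(identity) || identity < identity_floor)
    return(list(matched = FALSE, identity = identity,
                site_base = rep(NA_character_, nrow(sites))))
  pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  spos <- Biostrings::start(Biostrings::subject(pa))
  base_at <- rep(NA_character_, nrow(sites))
  if (nrow(sites)) {
    lookup <- setNames(seq_len(nrow(sites)), sites$column)
    s <- spos - 1L
    for (i in seq_along(sub)) {
      if (sub[i] != "-") {
        s <- s + 1L
        j <- lookup[as.character(s)]
        if (!is.na(j) && pat[i] != "-") base_at[j] <- pat[i]
      }
    }
  }
  list(matched = TRUE, identity = identity, site_base = base_at)
}

#' Classify an isoform from its M-site and P-site counts
#'
#' An isoform with fewer than \code{min_sites} scored diagnostic sites is
#' unassigned. Otherwise it is called subgenome M when its M-site
#' proportion strictly exceeds \code{hi} and it carries at least
#' \code{min_sites} M sites; subgenome P when the proportion is strictly
#' below \code{lo} with at least \code{min_sites} P sites; anything else
#' (boundary proportions included) is a recombinant and is removed from
#' tabulation.
#'
#' @param m_sites,p_sites non-negative integer counts.
#' @param th an [assignment_thresholds()].
#' @return one of \code{"M"}, \code{"P"}, \code{"recombinant"},
#'   \code{"unassigned"} (vectorised over the inputs).
#' @export
classify_isoform <- function(m_sites, p_sites, th = assignment_thresholds()) {
  stopifnot(all(m_sites >= 0), all(p_sites >= 0),
            inherits(th, "assignment_thresholds"))
  tot <- m_sites + p_sites
  prop <- ifelse(tot > 0, m_sites / tot, NA_real_)
  out <- rep("recombinant", length(tot))
  out[tot < th$min_sites] <- "unassigned"
  isM <- tot >= th$min_sites & prop > th$hi & m_sites >= th$min_sites
  isP <- tot >= th$min_sites & prop < th$lo & p_sites >= th$min_sites
  out[isM] <- "M"
  out[isP] <- "P"
  out
}

# Map isoforms to their best orthogroup by shared k-mers (prefilter before
# alignment; exact alignment only against the winning OG).
.match_isoforms_to_ogs <- function(isoforms, og_refs, k = 12L) {
  kmers <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1), k:n))
  }
  index <- new.env(hash = TRUE, parent = emptyenv())
  for (og in names(og_refs)) {
    for (km in kmers(og_refs[[og]])) {
      index[[km]] <- c(index[[km]], og)
    }
  }
  vapply(isoforms, function(s) {
    hits <- unlist(lapply(kmers(s), function(km) index[[km]]), use.names = FALSE)
    if (!length(hits)) return(NA_character_)
    tab <- table(hits)
    names(tab)[which.max(tab)]
  }, "")
}

#' Phase polyploid isoforms into parental subgenomes
#'
#' End-to-end phasing: finds diagnostic sites per orthogroup, matches each
#' isoform to its orthogroup (shared k-mer prefilter, then semi-global
#' alignment), scores the covered diagnostic columns against the parental
#' alleles, and classifies every isoform.
#'
#' @param isoforms named character vector of isoform sequences.
#' @param ogs an \code{og_set} (or any list of \code{og_id}/\code{aln}
#'   elements).
#' @param samples named character vector mapping isoform id to sample name
#'   (operational metadata; a single unnamed value recycles).
#' @param groups a [parental_groups()].
#' @param th an [assignment_thresholds()].
#' @param min_length,identity_floor passed to [align_isoform_to_og()].
#' @return data frame of class \code{isoform_assignments}: one row per
#'   isoform with \code{isoform_id}, \code{sample}, \code{og},
#'   \code{m_sites}, \code{p_sites}, \code{m_proportion}, \code{call}.
#'   Unmatched isoforms carry \code{og = NA} and call \code{"unassigned"}.
#' @export
phase_isoforms <- function(isoforms, ogs, samples = "S1",
                           groups = parental_groups(),
                           th = assignment_thresholds(),
                           min_length = 300L, identity_floor = 0.7) {
  if (is.null(names(isoforms))) .stopf("isoforms must be named")
  if (is.null(names(samples)) && length(samples) == 1L)
    samples <- setNames(rep(samples, length(isoforms)), names(isoforms))
  sites_by_og <- lapply(ogs, function(og) find_diagnostic_sites(og$aln, groups))
  refs <- lapply(ogs, function(og) og_consensus(og$aln))
  og_of <- .match_isoforms_to_ogs(isoforms, refs)
  rows <- lapply(names(isoforms), function(id) {
    og <- og_of[[id]]
    m_sites <- p_sites <- 0L
    call <- "unassigned"
    if (!is.na(og)) {
      sites <- sites_by_og[[og]]
      sc <- align_isoform_to_og(isoforms[[id]], refs[[og]], sites,
                                min_length = min_length,
                                identity_floor = identity_floor)
      if (sc$matched && nrow(sites)) {
        m_sites <- sum(sc$site_base == sites$m_allele, na.rm = TRUE)
        p_sites <- sum(sc$site_base == sites$p_allele, na.rm = TRUE)
        call <- classify_isoform(m_sites, p_sites, th)
      }
    }
    tot <- m_sites + p_sites
    data.frame(isoform_id = id, sample = unname(samples[id]),
               og = if (is.na(og)) NA_character_ else og,
               m_sites = m_sites, p_sites = p_sites,
               m_proportion = if (tot > 0) m_sites / tot else NA_real_,
               call = call, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("isoform_assignments", "data.frame")
  out
}

#' Tabulate homeolog expression classes per sample
#'
#' An orthogroup is H_MP for a sample when at least one isoform is called M
#' and at least one is called P; H_M (H_P) when only M-called (P-called)
#' isoforms are present. Recombinant and unassigned isoforms do not
#' contribute. Percentages are of the sample's total expressed orthogroups,
#' rounded half-up to integer percent.
#'
#' @param assignments an \code{isoform_assignments} data frame.
#' @return data frame with one row per sample: \code{sample}, \code{total},
#'   \code{H_MP}, \code{H_M}, \code{H_P} and \code{*_pct} columns; attribute
#'   \code{"og_classes"} holds the underlying per-(sample, og) class table.
#' @export
tabulate_homeologs <- function(assignments) {
  a <- assignments[assignments$call %in% c("M", "P") & !is.na(assignments$og), ]
  if (!nrow(a)) {
    out <- data.frame(sample = character(0), total = integer(0),
                      H_MP = integer(0), H_M = integer(0), H_P = integer(0),
                      H_MP_pct = numeric(0), H_M_pct = numeric(0),
                      H_P_pct = numeric(0))
    attr(out, "og_classes") <- data.frame(sample = character(0),
                                          og = character(0),
                                          class = character(0))
    return(out)
  }
  key <- paste(a$sample, a$og, sep = "\r")
  hasM <- tapply(a$call == "M", key, any)
  hasP <- tapply(a$call == "P", key, any)
  parts <- do.call(rbind, strsplit(names(hasM), "\r", fixed = TRUE))
  og_classes <- data.frame(sample = parts[, 1], og = parts[, 2],
                           class = ifelse(hasM & hasP, "H_MP",
                                          ifelse(hasM, "H_M", "H_P")),
                           stringsAsFactors = FALSE)
  rows <- lapply(split(og_classes, og_classes$sample), function(d) {
    n <- nrow(d)
    counts <- c(H_MP = sum(d$class == "H_MP"), H_M = sum(d$class == "H_M"),
                H_P = sum(d$class == "H_P"))
    data.frame(sample = d$sample[1], total = n,
               H_MP = counts[["H_MP"]], H_M = counts[["H_M"]],
               H_P = counts[["H_P"]],
               H_MP_pct = round_half_up(100 * counts[["H_MP"]] / n),
               H_M_pct = round_half_up(100 * counts[["H_M"]] / n),
               H_P_pct = round_half_up(100 * counts[["H_P"]] / n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "og_classes") <- og_classes
  out
}

#' Pairwise Pearson correlation of homeolog expression patterns
#'
#' Each sample's expression pattern over orthogroups is encoded as two
#' binary indicators per orthogroup (M expressed, P expressed). For each
#' sample pair the correlation is computed over orthogroups expressed in at
#' least one sample of the pair. A zero-variance vector yields \code{NA},
#' never 0.
#'
#' @param og_classes per-(sample, og) class table, e.g. the
#'   \code{"og_classes"} attribute of [tabulate_homeologs()].
#' @return symmetric matrix of Pearson coefficients (diagonal 1).
#' @export
pairwise_sample_correlation <- function(og_classes) {
  samples <- sort(unique(og_classes$sample))
  if (length(samples) < 2) .stopf("need at least 2 samples")
  ogs <- sort(unique(og_classes$og))
  enc <- function(s) {
    d <- og_classes[og_classes$sample == s, ]
    m <- setNames(rep(0L, length(ogs)), ogs)
    p <- m
    m[d$og[d$class %in% c("H_MP", "H_M")]] <- 1L
    p[d$og[d$class %in% c("H_MP", "H_P")]] <- 1L
    cbind(m, p)
  }
  encs <- lapply(setNames(samples, samples), enc)
  r <- matrix(NA_real_, length(samples), length(samples),
              dimnames = list(samples, samples))
  diag(r) <- 1
  for (i in seq_along(samples)) {
    for (j in seq_len(i - 1L)) {
      a <- encs[[i]]; b <- encs[[j]]
      keep <- rowSums(a) > 0 | rowSums(b) > 0
      va <- as.vector(a[keep, ]); vb <- as.vector(b[keep, ])
      if (sd(va) == 0 || sd(vb) == 0) next
      r[i, j] <- r[j, i] <- cor(va, vb)
    }
  }
  r
}
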