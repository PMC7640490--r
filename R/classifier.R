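# Five-way insertion sub-type classification. Each inserted sequence is
# scanned for tandem structure, aligned against a mobile-element consensus
# library, against its own flanks (tandem-duplication evidence) and against
# the genome excluding the flank windows (dispersed-duplication evidence);
# the decision tree assigns at most one label using a minimal coverage
# threshold.

INSERTION_TYPES <- c("tandem_repeat", "mobile_element", "tandem_duplication",
                     "dispersed_duplication", "novel_sequence")

#' Classifier configuration
#'
#' @param min_cov minimal fraction of the inserted sequence that the
#'   type-specific evidence must cover, as one contiguous segment (novel
#'   sequence: as total unaligned fraction). Default 0.80.
#' @param min_identity minimum alignment identity for all evidence
#'   alignments (default 0.90).
#' @param dispersed_copy_max dispersed duplications must have a genomic copy
#'   number strictly below this (default 50); higher counts are in the
#'   mobile-element range.
#' @param max_flank flank-window cap in bp for tandem-duplication evidence
#'   (windows are otherwise the same size as the insertion).
#' @param segment_gap maximal gap in bp bridged when merging same-type
#'   alignment blocks into one contiguous segment (sequencing-error
#'   tolerance).
#' @param priority evaluation order of the decision tree.
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(min_cov = 0.80, min_identity = 0.90,
                              dispersed_copy_max = 50L, max_flank = 10000L,
                              segment_gap = 10L,
                              priority = INSERTION_TYPES) {
  stopifnot(min_cov > 0, min_cov <= 1)
  stopifnot(all(sort(priority) == sort(INSERTION_TYPES)))
  structure(list(min_cov = min_cov, min_identity = min_identity,
                 dispersed_copy_max = as.integer(dispersed_copy_max),
                 max_flank = as.integer(max_flank),
                 segment_gap = as.integer(segment_gap), priority = priority),
            class = "classifier_config")
}

#' Per-type evidence coverage of one insertion
#'
#' Computes, for one resolved insertion, the fraction of the inserted
#' sequence covered by each evidence class: tandem-repeat arrays (from
#' [find_tandem_structure()]), mobile-element consensus alignments, tandem
#' duplication (alignments of the two flanking sequences, each the same size
#' as the insertion, against the inserted sequence), dispersed duplication
#' (genome alignments excluding the flank windows), plus the unaligned
#' fraction and the genomic copy count. Alignment-based coverages are the
#' longest contiguous merged segment (gaps up to `cfg$segment_gap` bridged)
#' divided by the insertion length; the unaligned fraction is one minus the
#' union of all aligned/annotated bases.
#'
#' Insertions shorter than 20 bp cannot be aligned by the seed-and-extend
#' engine; their coverage is computed from the tandem scan only, with a
#' warning.
#'
#' @param chrom,pos insertion site (anchor base).
#' @param ins inserted sequence.
#' @param genome genome (`DNAStringSet`, named character, or coercible).
#' @param me_library mobile-element consensus `DNAStringSet` (or named
#'   character vector).
#' @param cfg a [classifier_config()].
#' @return list with `cov_tandem_repeat`, `cov_mobile_element`,
#'   `cov_tandem_dup`, `cov_dispersed_dup`, `cov_unaligned`,
#'   `genomic_copy_count`, `tr_seed_size`.
#' @export
annotate_components <- function(chrom, pos, ins, genome, me_library,
                                cfg = classifier_config()) {
  genome <- .genome_chars(genome)
  me_library <- .genome_chars(me_library)
  li <- nchar(ins)
  stopifnot(li >= 1)
  g <- .chrom_seq(genome, chrom)
  lg <- nchar(g)

  # tandem structure
  tr <- find_tandem_structure(ins, min_coverage = 0.1)
  cov_tr <- if (nrow(tr)) tr$coverage[1] else 0
  tr_seed <- if (nrow(tr)) tr$seed_size[1] else NA_integer_
  tr_int <- if (nrow(tr)) list(c(tr$span_start[1], tr$span_end[1])) else list()

  if (li < 20) {
    warning("insertion shorter than 20 bp: alignment-based evidence skipped")
    return(list(cov_tandem_repeat = cov_tr, cov_mobile_element = 0,
                cov_tandem_dup = 0, cov_dispersed_dup = 0,
                cov_unaligned = 1 - (if (nrow(tr)) (tr$span_end[1] - tr$span_start[1] + 1) / li else 0),
                genomic_copy_count = 0L, tr_seed_size = tr_seed))
  }

  covered <- list()  # intervals on ins covered by any evidence
  if (nrow(tr)) {
    covered <- c(covered, lapply(seq_len(nrow(tr)), function(i) c(tr$span_start[i], tr$span_end[i])))
  }

  # mobile-element evidence: ins vs each consensus; coverage of ins (query)
  me_q <- list()
  for (cons in me_library) {
    al <- local_align(ins, cons, min_identity = cfg$min_identity)
    if (nrow(al)) me_q <- c(me_q, lapply(seq_len(nrow(al)), function(i) c(al$query_start[i], al$query_end[i])))
  }
  cov_me <- .longest_segment(vapply(me_q, `[`, 0, 1), vapply(me_q, `[`, 0, 2),
                             li, gap = cfg$segment_gap) / li
  covered <- c(covered, me_q)

  # tandem-duplication evidence: flanks (same size as insertion, capped)
  # aligned against the inserted sequence; coverage of ins (target)
  w <- min(li, cfg$max_flank)
  td_q <- list()
  lw_start <- max(1L, pos - w + 1L)
  left_window <- substr(g, lw_start, pos)
  right_window <- substr(g, pos + 1L, min(lg, pos + w))
  for (flank in c(left_window, right_window)) {
    if (nchar(flank) < 20) next
    al <- local_align(flank, ins, min_identity = cfg$min_identity)
    if (nrow(al)) td_q <- c(td_q, lapply(seq_len(nrow(al)), function(i) c(al$target_start[i], al$target_end[i])))
  }
  cov_td <- .longest_segment(vapply(td_q, `[`, 0, 1), vapply(td_q, `[`, 0, 2),
                             li, gap = cfg$segment_gap) / li
  covered <- c(covered, td_q)

  # genome alignments: dispersed evidence excludes the flank windows
  flank_lo <- lw_start
  flank_hi <- min(lg, pos + w)
  dd_q <- list()
  n_loci <- 0L
  for (chr in names(genome)) {
    al <- local_align(ins, genome[[chr]], min_identity = cfg$min_identity)
    if (!nrow(al)) next
    in_flank <- chr == chrom & al$target_start <= flank_hi & al$target_end >= flank_lo
    out_fl <- al[!in_flank, , drop = FALSE]
    if (nrow(out_fl)) {
      dd_q <- c(dd_q, lapply(seq_len(nrow(out_fl)), function(i) c(out_fl$query_start[i], out_fl$query_end[i])))
    }
    qcov <- (al$query_end - al$query_start + 1L) / li
    n_loci <- n_loci + sum(qcov >= cfg$min_cov)
  }
  cov_dd <- .longest_segment(vapply(dd_q, `[`, 0, 1), vapply(dd_q, `[`, 0, 2),
                             li, gap = cfg$segment_gap) / li
  covered <- c(covered, dd_q)

  cov_un <- 1 - .union_coverage(vapply(covered, `[`, 0, 1), vapply(covered, `[`, 0, 2), li) / li

  list(cov_tandem_repeat = cov_tr, cov_mobile_element = cov_me,
       cov_tandem_dup = cov_td, cov_dispersed_dup = cov_dd,
       cov_unaligned = cov_un, genomic_copy_count = n_loci,
       tr_seed_size = tr_seed)
}

#' Assign an insertion sub-type from its component annotation
#'
#' Applies the decision tree in priority order (default: tandem repeat,
#' mobile element, tandem duplication, dispersed duplication, novel
#' sequence): the first type whose coverage reaches `cfg$min_cov` wins;
#' dispersed duplication additionally requires a genomic copy count strictly
#' below `cfg$dispersed_copy_max` (to not be confounded with mobile
#' elements). Records reaching no threshold are `unassigned`, with their
#' partial coverages reported in decreasing order.
#'
#' @param ca component annotation from [annotate_components()].
#' @param cfg a [classifier_config()].
#' @return list with `label` and, for unassigned records, `partial_labels`
#'   (data.frame of type/coverage sorted decreasing).
#' @export
classify <- function(ca, cfg = classifier_config()) {
  covs <- c(tandem_repeat = ca$cov_tandem_repeat,
            mobile_element = ca$cov_mobile_element,
            tandem_duplication = ca$cov_tandem_dup,
            dispersed_duplication = ca$cov_dispersed_dup,
            novel_sequence = ca$cov_unaligned)
  for (ty in cfg$priority) {
    if (covs[[ty]] >= cfg$min_cov) {
      if (ty == "dispersed_duplication" && ca$genomic_copy_count >= cfg$dispersed_copy_max) next
      return(list(label = ty, partial_labels = NULL))
    }
  }
  pl <- data.frame(type = names(covs), coverage = unname(covs), stringsAsFactors = FALSE)
  pl <- pl[order(-pl$coverage), , drop = FALSE]
  rownames(pl) <- NULL
  list(label = "unassigned", partial_labels = pl)
}

#' Classify every record of a callset
#'
#' Runs [annotate_components()] + [classify()] per record. Per-record errors
#' are caught, reported in the `error` column, and never abort the run.
#'
#' @param cs an `inschar_callset` of resolved records.
#' @param genome genome.
#' @param me_library mobile-element consensus library.
#' @param cfg a [classifier_config()].
#' @return data.frame with one row per record: `record_id`, `label`, the five
#'   coverages, `genomic_copy_count`, `tr_seed_size`, `error`. Summary counts
#'   by label are attached as attribute `label_counts`.
#' @export
classify_callset <- function(cs, genome, me_library, cfg = classifier_config()) {
  stopifnot(inherits(cs, "inschar_callset"))
  genome <- .genome_chars(genome)
  me_library <- .genome_chars(me_library)
  r <- cs$records
  rows <- lapply(seq_len(nrow(r)), function(i) {
    res <- tryCatch({
      ca <- suppressWarnings(annotate_components(r$chrom[i], r$pos[i], r$inserted_seq[i],
                                                 genome, me_library, cfg))
      cl <- classify(ca, cfg)
      data.frame(record_id = r$record_id[i], label = cl$label,
                 cov_tandem_repeat = ca$cov_tandem_repeat,
                 cov_mobile_element = ca$cov_mobile_element,
                 cov_tandem_dup = ca$cov_tandem_dup,
                 cov_dispersed_dup = ca$cov_dispersed_dup,
                 cov_unaligned = ca$cov_unaligned,
                 genomic_copy_count = ca$genomic_copy_count,
                 tr_seed_size = ca$tr_seed_size,
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(record_id = r$record_id[i], label = NA_character_,
                 cov_tandem_repeat = NA_real_, cov_mobile_element = NA_real_,
                 cov_tandem_dup = NA_real_, cov_dispersed_dup = NA_real_,
                 cov_unaligned = NA_real_, genomic_copy_count = NA_integer_,
                 tr_seed_size = NA_integer_, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    res
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(record_id = character(0), label = character(0),
               cov_tandem_repeat = numeric(0), cov_mobile_element = numeric(0),
               cov_tandem_dup = numeric(0), cov_dispersed_dup = numeric(0),
               cov_unaligned = numeric(0), genomic_copy_count = integer(0),
               tr_seed_size = integer(0), error = character(0),
               stringsAsFactors = FALSE)
  attr(out, "label_counts") <- table(factor(out$label, levels = c(INSERTION_TYPES, "unassigned")))
  out
}
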