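# Callset-level characterization: joint per-record tables of insertion type,
# size class, genomic context, junctional homology and discovery technology,
# plus cross-callset sharing estimates.

SIZE_BREAKS <- c(0, 250, 500, 1000, Inf)
SIZE_LABELS <- c("[50,250)", "[250,500)", "[500,1000)", ">=1000")
HOMOLOGY_BREAKS <- c(-Inf, 10, 50, Inf)
HOMOLOGY_LABELS <- c("<=10", "(10,50]", ">50")

#' Per-record feature table and axis summaries for a callset
#'
#' Runs the classifier, the homology detector, the context annotator and the
#' discovery-technology parser over every record and tabulates counts and
#' fractions along each axis (type, size class, repeat context, homology
#' class), optionally stratified by discovery technology.
#'
#' @param cs a filtered `inschar_callset`.
#' @param genome genome.
#' @param tracks an `annotation_tracks` object.
#' @param me_library mobile-element consensus library.
#' @param cfg a [classifier_config()].
#' @param size_breaks,homology_breaks bin edges (defaults follow the
#'   250/500/1000 bp and 10/50 bp conventions).
#' @return list of class `feature_summary`: `per_record` (data.frame),
#'   `by_type`, `by_size`, `by_context`, `by_homology` (data.frames of
#'   count/fraction, plus the short-read fraction per class when discovery
#'   tags are present).
#' @export
summarize_callset <- function(cs, genome, tracks, me_library,
                              cfg = classifier_config(),
                              size_breaks = SIZE_BREAKS,
                              homology_breaks = HOMOLOGY_BREAKS) {
  stopifnot(inherits(cs, "inschar_callset"))
  genome <- .genome_chars(genome)
  cl <- classify_callset(cs, genome, me_library, cfg)
  hom <- callset_homology(cs, genome)
  ctx <- classify_site(cs$records$chrom, cs$records$pos, tracks)
  disc <- parse_discovery_technology(cs)
  per <- data.frame(
    record_id = cs$records$record_id,
    size = cs$records$size,
    label = cl$label,
    size_class = cut(cs$records$size, size_breaks, labels = SIZE_LABELS, right = FALSE),
    repeat_context = ctx$repeat_context,
    genic_context = ctx$genic_context,
    homology = hom$total_size,
    homology_class = cut(hom$total_size, homology_breaks, labels = HOMOLOGY_LABELS),
    discovery = disc,
    stringsAsFactors = FALSE)
  axis_tab <- function(f) {
    tb <- table(f)
    n <- sum(tb)
    data.frame(class = names(tb), count = as.integer(tb),
               fraction = if (n) as.numeric(tb) / n else rep(NA_real_, length(tb)),
               sr_fraction = vapply(names(tb), function(k) {
                 sel <- !is.na(f) & f == k
                 if (!sum(sel)) return(NA_real_)
                 mean(per$discovery[sel] == "short_read")
               }, numeric(1)),
               stringsAsFactors = FALSE)
  }
  out <- list(per_record = per,
              by_type = axis_tab(factor(per$label, levels = c(INSERTION_TYPES, "unassigned"))),
              by_size = axis_tab(per$size_class),
              by_context = axis_tab(per$repeat_context),
              by_homology = axis_tab(per$homology_class))
  class(out) <- "feature_summary"
  out
}

#' Short-read discovery fraction per feature class
#'
#' For each class of the chosen axis, the fraction of its records whose
#' discovery-technology tag credits short reads. Classes with no members are
#' reported as `NA` (undefined), not 0.
#'
#' @param per_record the `per_record` table of a [summarize_callset()]
#'   result (or any data.frame with a `discovery` column and the axis
#'   column).
#' @param axis column name to stratify on (e.g. `"label"`, `"size_class"`,
#'   `"repeat_context"`, `"homology_class"`).
#' @return data.frame with `class`, `n`, `n_short_read`, `sr_fraction`.
#' @export
stratified_sr_recall <- function(per_record, axis = "label") {
  stopifnot(axis %in% names(per_record), "discovery" %in% names(per_record))
  f <- per_record[[axis]]
  if (!is.factor(f)) f <- factor(f)
  out <- lapply(levels(f), function(k) {
    sel <- !is.na(f) & f == k
    n <- sum(sel)
    nsr <- sum(per_record$discovery[sel] == "short_read")
    data.frame(class = k, n = n, n_short_read = nsr,
               sr_fraction = if (n) nsr / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Count insertion sites shared between two callsets
#'
#' One-to-one greedy nearest matching of insertion sites; two sites are the
#' same variant when strictly less than `window` bp apart. Symmetric in its
#' arguments.
#'
#' @param a,b `inschar_callset`s.
#' @param window sharing window in bp (default 1000).
#' @return integer count of shared sites.
#' @export
shared_insertions <- function(a, b, window = 1000L) {
  ra <- a$records; rb <- b$records
  if (!nrow(ra) || !nrow(rb)) return(0L)
  cand <- list()
  for (i in seq_len(nrow(ra))) {
    same <- which(rb$chrom == ra$chrom[i])
    if (!length(same)) next
    d <- abs(rb$pos[same] - ra$pos[i])
    ok <- d < window
    if (any(ok)) cand[[length(cand) + 1]] <- data.frame(ai = i, bi = same[ok], dist = d[ok])
  }
  if (!length(cand)) return(0L)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$dist, ra$pos[cand$ai], rb$pos[cand$bi]), , drop = FALSE]
  used_a <- rep(FALSE, nrow(ra)); used_b <- rep(FALSE, nrow(rb))
  count <- 0L
  for (k in seq_len(nrow(cand))) {
    if (used_a[cand$ai[k]] || used_b[cand$bi[k]]) next
    used_a[cand$ai[k]] <- TRUE; used_b[cand$bi[k]] <- TRUE
    count <- count + 1L
  }
  count
}

#' Count insertion sites common to every callset
#'
#' Pools all sites, clusters them by single linkage (adjacent sites strictly
#' less than `window` bp apart join the same cluster) and counts clusters
#' containing at least one site from every callset — a rough multi-way
#' sharing estimate.
#'
#' @param callsets list of at least two `inschar_callset`s.
#' @param window clustering window in bp (default 1000).
#' @return integer count of universal clusters.
#' @export
multiway_common <- function(callsets, window = 1000L) {
  stopifnot(length(callsets) >= 2)
  if (any(vapply(callsets, function(cs) nrow(cs$records) == 0, logical(1)))) return(0L)
  pool <- do.call(rbind, lapply(seq_along(callsets), function(i) {
    data.frame(chrom = callsets[[i]]$records$chrom, pos = callsets[[i]]$records$pos,
               set = i, stringsAsFactors = FALSE)
  }))
  pool <- pool[order(pool$chrom, pool$pos), , drop = FALSE]
  new_cluster <- c(TRUE, pool$chrom[-1] != pool$chrom[-nrow(pool)] |
                     diff(pool$pos) >= window)
  cl <- cumsum(new_cluster)
  nsets <- length(callsets)
  sum(vapply(split(pool$set, cl), function(s) length(unique(s)) == nsets, logical(1)))
}
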