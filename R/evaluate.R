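# Scoring of predicted insertion callsets against a truth set: insertion-site
# recall (10 bp positional margin) and sequence-resolved recall (site match
# plus >= 90% end-to-end identity and +/- 10% size), absolute false-positive
# counts, and multi-caller union/intersection accounting.

#' Matching configuration for recall evaluation
#'
#' @param site_margin maximal distance in bp between predicted and true
#'   anchor positions (default 10).
#' @param min_identity minimal end-to-end identity between predicted and
#'   true inserted sequences (default 0.90; long-read evaluations often use
#'   0.80).
#' @param size_tolerance allowed relative size deviation (default 0.10).
#' @param min_call_size calls must be strictly larger than this (default 50).
#' @param pass_only keep only FILTER == PASS calls (default TRUE; "." counts
#'   as PASS).
#' @export
match_config <- function(site_margin = 10L, min_identity = 0.90,
                         size_tolerance = 0.10, min_call_size = 50L,
                         pass_only = TRUE) {
  stopifnot(site_margin >= 0, size_tolerance >= 0, size_tolerance < 1)
  structure(list(site_margin = as.integer(site_margin), min_identity = min_identity,
                 size_tolerance = size_tolerance, min_call_size = as.integer(min_call_size),
                 pass_only = pass_only), class = "match_config")
}

#' Filter calls before recall computation
#'
#' Retains resolved calls strictly larger than `min_call_size` and, when
#' `pass_only` is set, calls with FILTER `PASS` (or `.`). Symbolic calls are
#' retained for later sequence resolution.
#'
#' @param calls an `inschar_callset`.
#' @param cfg a [match_config()].
#' @return the filtered callset.
#' @export
filter_calls <- function(calls, cfg = match_config()) {
  stopifnot(inherits(calls, "inschar_callset"))
  r <- calls$records
  keep <- !r$resolved | r$size > cfg$min_call_size
  if (cfg$pass_only) keep <- keep & (r$filter %in% c("PASS", "."))
  callset(r[keep, , drop = FALSE], convention = calls$convention,
          source_label = calls$source_label)
}

#' Resolve a symbolic duplication call from the reference
#'
#' Fills the inserted sequence of a symbolic call from reference coordinates
#' of the duplicated copy carried in INFO as `DUPCOORDS=chrom:start-end`
#' (1-based, inclusive). Calls without usable coordinates stay unresolved
#' and remain eligible for site-only matching.
#'
#' @param calls an `inschar_callset`.
#' @param genome genome.
#' @param coords_tag INFO key carrying the copy coordinates.
#' @return the callset with resolvable records filled in.
#' @export
resolve_symbolic <- function(calls, genome, coords_tag = "DUPCOORDS") {
  stopifnot(inherits(calls, "inschar_callset"))
  genome <- .genome_chars(genome)
  r <- calls$records
  for (i in which(!r$resolved)) {
    co <- .info_tag(r$info[i], coords_tag)
    if (is.na(co)) next
    m <- regmatches(co, regexec("^([^:]+):([0-9]+)-([0-9]+)$", co))[[1]]
    if (length(m) != 4) next
    chrom <- m[2]; s <- as.integer(m[3]); e <- as.integer(m[4])
    if (!chrom %in% names(genome)) next
    if (s < 1 || e < s || e > nchar(genome[[chrom]])) next
    r$inserted_seq[i] <- substr(genome[[chrom]], s, e)
    r$size[i] <- e - s + 1L
    r$resolved[i] <- TRUE
  }
  callset(r, convention = calls$convention, source_label = calls$source_label)
}

#' Match calls against a truth set and score recall
#'
#' Greedy one-to-one matching: candidate (truth, call) pairs within the site
#' margin are assigned in order of increasing distance (ties: leftmost truth
#' position, then leftmost call), so no call validates two truths and the
#' result does not depend on input order. A matched pair is a site true
#' positive; it is additionally a sequence-resolved true positive when the
#' call is resolved, shares at least `min_identity` end-to-end identity with
#' the true inserted sequence and deviates in size by at most
#' `size_tolerance` of the true size. Retained calls matching no truth are
#' false positives, reported as an absolute count.
#'
#' @param truth truth data.frame (`chrom`, `pos`, `inserted_seq`) or an
#'   `inschar_callset`.
#' @param calls an `inschar_callset` (already filtered with
#'   [filter_calls()], or pass `filter = TRUE`).
#' @param cfg a [match_config()].
#' @param filter apply [filter_calls()] first (default TRUE).
#' @return a `recall_report` list: `n_truth`, `n_calls_considered`,
#'   `n_tp_site`, `n_tp_seq`, `n_fp`, `recall_site`, `recall_seq`,
#'   `pass_only`, plus `tp_truth_ids` (record ids of site-validated truths)
#'   and `matches` (data.frame of assigned pairs).
#' @export
match_and_score <- function(truth, calls, cfg = match_config(), filter = TRUE) {
  if (inherits(truth, "inschar_callset")) truth <- truth$records
  stopifnot(inherits(calls, "inschar_callset"))
  if (filter) calls <- filter_calls(calls, cfg)
  cr <- calls$records
  if (nrow(cr) && nrow(truth)) {
    missing_chrom <- setdiff(unique(cr$chrom), unique(truth$chrom))
    common <- intersect(unique(cr$chrom), unique(truth$chrom))
    if (length(common) == 0) {
      stop("no chromosome shared between truth and calls; call chromosomes: ",
           paste(missing_chrom, collapse = ", "))
    }
  }
  tid <- if ("record_id" %in% names(truth)) truth$record_id else
    paste0(truth$chrom, ":", truth$pos)
  # candidate pairs within margin
  cand <- list()
  for (i in seq_len(nrow(truth))) {
    same <- which(cr$chrom == truth$chrom[i])
    if (!length(same)) next
    d <- abs(cr$pos[same] - truth$pos[i])
    ok <- d <= cfg$site_margin
    if (any(ok)) {
      cand[[length(cand) + 1]] <- data.frame(ti = i, ci = same[ok], dist = d[ok])
    }
  }
  matches <- data.frame(ti = integer(0), ci = integer(0), dist = integer(0))
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand$dist, truth$pos[cand$ti], cr$pos[cand$ci]), , drop = FALSE]
    used_t <- rep(FALSE, nrow(truth)); used_c <- rep(FALSE, nrow(cr))
    keep <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      if (used_t[cand$ti[k]] || used_c[cand$ci[k]]) next
      used_t[cand$ti[k]] <- TRUE; used_c[cand$ci[k]] <- TRUE
      keep[k] <- TRUE
    }
    matches <- cand[keep, , drop = FALSE]
  }
  n_tp_site <- nrow(matches)
  seq_ok <- logical(n_tp_site)
  if (n_tp_site) {
    for (k in seq_len(n_tp_site)) {
      i <- matches$ti[k]; j <- matches$ci[k]
      if (!cr$resolved[j]) next
      ts <- nchar(truth$inserted_seq[i])
      if (abs(cr$size[j] - ts) > cfg$size_tolerance * ts) next
      if (global_identity(cr$inserted_seq[j], truth$inserted_seq[i]) < cfg$min_identity) next
      seq_ok[k] <- TRUE
    }
  }
  n_truth <- nrow(truth)
  out <- list(
    n_truth = n_truth,
    n_calls_considered = nrow(cr),
    n_tp_site = n_tp_site,
    n_tp_seq = sum(seq_ok),
    n_fp = nrow(cr) - n_tp_site,
    recall_site = if (n_truth) n_tp_site / n_truth else NA_real_,
    recall_seq = if (n_truth) sum(seq_ok) / n_truth else NA_real_,
    pass_only = cfg$pass_only,
    tp_truth_ids = tid[matches$ti],
    tp_truth_ids_seq = tid[matches$ti[seq_ok]],
    matches = matches)
  class(out) <- "recall_report"
  out
}

#' @export
print.recall_report <- function(x, ...) {
  cat(sprintf("Recall report: %d truth, %d calls | site TP %d (%.1f%%) | seq TP %d (%.1f%%) | FP %d\n",
              x$n_truth, x$n_calls_considered, x$n_tp_site, 100 * x$recall_site,
              x$n_tp_seq, 100 * x$recall_seq, x$n_fp))
  invisible(x)
}

#' Combine several callers against one truth set
#'
#' Scores each callset independently, then intersects and unites the
#' truth-indexed site-TP sets and counts how many truths are validated by
#' exactly k of the n callers.
#'
#' @param callsets named list of at least two `inschar_callset`s.
#' @param truth truth data.frame or callset.
#' @param cfg a [match_config()].
#' @return list with `reports` (per caller), `union_count`,
#'   `intersection_count`, `k_of_n` (integer vector indexed by k), and
#'   `union_ids` / `intersection_ids`.
#' @export
combine_callsets <- function(callsets, truth, cfg = match_config()) {
  stopifnot(length(callsets) >= 2)
  if (is.null(names(callsets))) names(callsets) <- paste0("caller", seq_along(callsets))
  reports <- lapply(callsets, function(cs) match_and_score(truth, cs, cfg))
  tp_sets <- lapply(reports, `[[`, "tp_truth_ids")
  union_ids <- Reduce(union, tp_sets)
  inter_ids <- Reduce(intersect, tp_sets)
  all_ids <- unlist(tp_sets)
  kcounts <- table(table(all_ids))
  k_of_n <- stats::setNames(integer(length(callsets)), seq_along(callsets))
  k_of_n[names(kcounts)] <- as.integer(kcounts)
  list(reports = reports, union_count = length(union_ids),
       intersection_count = length(inter_ids), k_of_n = k_of_n,
       union_ids = union_ids, intersection_ids = inter_ids)
}
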