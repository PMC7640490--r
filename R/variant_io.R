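#' Insertion callset container
#'
#' A callset is an ordered table of sequence-resolved insertion records plus
#' the convention of the study that produced it. Records carry the VCF anchor
#' position (1-based position of the reference base immediately preceding the
#' inserted sequence), the inserted sequence itself, and the raw FILTER, INFO
#' and genotype fields needed by downstream filters and discovery-technology
#' parsing.
#'
#' @param records data.frame with columns `record_id`, `chrom`, `pos`,
#'   `inserted_seq`, `size`, `filter`, `info`, `genotype`, `resolved`.
#' @param convention one of `"generic"`, `"chaisson"`, `"giab"` — the INFO/tag
#'   dialect used by the study.
#' @param source_label free-text label for reports.
#' @return an object of class `inschar_callset`.
#' @export
callset <- function(records = .empty_records(), convention = c("generic", "chaisson", "giab"),
                    source_label = "") {
  convention <- match.arg(convention)
  stopifnot(is.data.frame(records))
  need <- c("record_id", "chrom", "pos", "inserted_seq", "size", "filter",
            "info", "genotype", "resolved")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) stop("records missing columns: ", paste(missing_cols, collapse = ", "))
  records$pos <- as.integer(records$pos)
  records$size <- as.integer(records$size)
  if (nrow(records)) {
    bad <- records$resolved & (nchar(records$inserted_seq) != records$size | records$size < 1)
    if (any(bad)) stop("size must equal nchar(inserted_seq) and be >= 1 for resolved records")
    if (any(records$pos < 1)) stop("pos must be >= 1")
    if (any(records$resolved & grepl("[^ACGTN]", records$inserted_seq))) {
      stop("inserted_seq may only contain A, C, G, T, N")
    }
    records <- records[order(records$chrom, records$pos), , drop = FALSE]
    rownames(records) <- NULL
  }
  structure(list(records = records, convention = convention, source_label = source_label),
            class = "inschar_callset")
}

#' @export
print.inschar_callset <- function(x, ...) {
  cat("Insertion callset (", x$convention, "): ", nrow(x$records), " records",
      if (nzchar(x$source_label)) paste0(" [", x$source_label, "]"), "\n", sep = "")
  invisible(x)
}

#' @export
length.inschar_callset <- function(x) nrow(x$records)

#' Gold-standard filtering configuration
#'
#' Mirrors the filters applied to published sequence-resolved insertion
#' callsets: minimum size (insertions must be larger than `min_size`),
#' sequence resolution, support in at least one parent of the trio, core
#' genome restriction via a chromosome allow-list, and (GiaB convention)
#' removal of calls flagged `LongHomRef` by long-read genotyping.
#'
#' @param min_size size threshold in bp; retained insertions are strictly
#'   larger (default 50).
#' @param require_sequence_resolved drop symbolic/unresolved records.
#' @param require_parent_support require the parent-support INFO key.
#' @param drop_longhomref drop records whose FILTER contains "LongHomRef"
#'   (GiaB convention only).
#' @param chrom_allowlist optional character vector of chromosomes defining
#'   the core genome; `NULL` keeps all.
#' @param parent_info_key INFO key carrying per-parent genotype/support.
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_size = 50, require_sequence_resolved = TRUE,
                          require_parent_support = FALSE, drop_longhomref = TRUE,
                          chrom_allowlist = NULL, parent_info_key = "PARENTS") {
  stopifnot(min_size >= 0)
  structure(list(min_size = min_size,
                 require_sequence_resolved = require_sequence_resolved,
                 require_parent_support = require_parent_support,
                 drop_longhomref = drop_longhomref,
                 chrom_allowlist = chrom_allowlist,
                 parent_info_key = parent_info_key),
            class = "filter_config")
}

#' Read insertion records from a VCF file
#'
#' Extracts insertion variants from a VCF 4.x file (plain or gzipped). Every
#' ALT allele longer than REF by at least 1 bp, where REF is a prefix of ALT,
#' yields one record whose inserted sequence is ALT minus the shared anchor
#' base(s). Symbolic `<INS>`-style ALTs are retained as unresolved records
#' with an empty inserted sequence. Multi-allelic records are split into one
#' record per insertion allele. Non-insertion records (SNVs, deletions) are
#' skipped; nothing that qualifies as an insertion is silently dropped.
#'
#' @param path VCF file path.
#' @param convention callset convention, see [callset()].
#' @param source_label label stored on the callset (defaults to the file name).
#' @return an `inschar_callset`. Records whose REF disagrees with the ALT
#'   prefix are collected in `attr(, "record_errors")` rather than aborting.
#' @export
read_vcf_insertions <- function(path, convention = c("generic", "chaisson", "giab"),
                                source_label = basename(path)) {
  convention <- match.arg(convention)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF '", path, "': ", conditionMessage(e)))
  fix <- v@fix
  gt <- v@gt
  n <- nrow(fix)
  if (is.null(n) || n == 0) {
    return(callset(convention = convention, source_label = source_label))
  }
  rows <- vector("list", n)
  errors <- character(0)
  for (i in seq_len(n)) {
    chrom <- fix[i, "CHROM"]; pos <- as.integer(fix[i, "POS"])
    ref <- fix[i, "REF"]; alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    id <- fix[i, "ID"]; filt <- fix[i, "FILTER"]; info <- fix[i, "INFO"]
    if (is.na(filt)) filt <- "."
    if (is.na(info)) info <- "."
    geno <- "."
    if (!is.null(gt) && ncol(gt) >= 2) {
      fmt <- strsplit(gt[i, 1], ":", fixed = TRUE)[[1]]
      val <- strsplit(gt[i, 2], ":", fixed = TRUE)[[1]]
      gti <- match("GT", fmt)
      if (!is.na(gti) && gti <= length(val)) geno <- val[gti]
    }
    sub <- list()
    for (j in seq_along(alts)) {
      alt <- alts[j]
      rid <- if (!is.na(id) && id != ".") id else paste0(chrom, ":", pos)
      if (length(alts) > 1) rid <- paste0(rid, "_", j)
      if (grepl("^<", alt)) {
        if (!grepl("INS|DUP", alt)) next  # symbolic non-insertion
        sub[[length(sub) + 1]] <- data.frame(
          record_id = rid, chrom = chrom, pos = pos, inserted_seq = "",
          size = 0L, filter = filt, info = info, genotype = geno,
          resolved = FALSE, stringsAsFactors = FALSE)
      } else if (nchar(alt) > nchar(ref)) {
        if (!startsWith(toupper(alt), toupper(ref))) {
          errors <- c(errors, paste0("record ", rid, ": REF '", ref,
                                     "' is not a prefix of longer ALT '", alt, "'"))
          next
        }
        ins <- toupper(substr(alt, nchar(ref) + 1L, nchar(alt)))
        sub[[length(sub) + 1]] <- data.frame(
          record_id = rid, chrom = chrom, pos = pos, inserted_seq = ins,
          size = nchar(ins), filter = filt, info = info, genotype = geno,
          resolved = TRUE, stringsAsFactors = FALSE)
      }
    }
    if (length(sub)) rows[[i]] <- do.call(rbind, sub)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  rec <- if (length(rows)) do.call(rbind, rows) else .empty_records()
  cs <- callset(rec, convention = convention, source_label = source_label)
  attr(cs, "record_errors") <- errors
  cs
}

#' Apply gold-standard callset filters
#'
#' Retains records that are larger than `min_size` bp, sequence resolved,
#' located on the core genome (chromosome allow-list), supported in a parent
#' (when required and the tag convention provides it), and — for the GiaB
#' convention — not flagged `LongHomRef`. A per-filter removal count is
#' attached as attribute `removal_counts`; filters are applied in the order
#' core genome, size, resolution, LongHomRef, parent support, and each record
#' is charged to the first filter that removes it.
#'
#' @param cs an `inschar_callset`.
#' @param cfg a [filter_config()].
#' @return the filtered callset with attribute `removal_counts` (named
#'   integer vector).
#' @export
apply_goldstandard_filters <- function(cs, cfg = filter_config()) {
  stopifnot(inherits(cs, "inschar_callset"), inherits(cfg, "filter_config"))
  r <- cs$records
  if (cs$convention == "giab" && nrow(r) && all(is.na(r$filter))) {
    stop("giab convention requires FILTER fields")
  }
  counts <- c(core_genome = 0L, size = 0L, unresolved = 0L, longhomref = 0L, parent = 0L)
  keep <- rep(TRUE, nrow(r))
  removed_by <- function(cond, label) {
    hit <- keep & cond
    counts[label] <<- counts[label] + sum(hit)
    keep <<- keep & !cond
  }
  if (nrow(r)) {
    if (!is.null(cfg$chrom_allowlist)) {
      removed_by(!(r$chrom %in% cfg$chrom_allowlist), "core_genome")
    }
    removed_by(r$resolved & r$size <= cfg$min_size, "size")
    if (cfg$require_sequence_resolved) removed_by(!r$resolved, "unresolved")
    if (cfg$drop_longhomref && cs$convention == "giab") {
      removed_by(grepl("LongHomRef", r$filter, fixed = TRUE), "longhomref")
    }
    if (cfg$require_parent_support) {
      parent <- .info_tag(r$info, cfg$parent_info_key)
      removed_by(is.na(parent) | parent %in% c(".", "0/0", "./."), "parent")
    }
  }
  out <- callset(r[keep, , drop = FALSE], convention = cs$convention,
                 source_label = cs$source_label)
  attr(out, "removal_counts") <- counts
  out
}

#' Discovery-technology parsing configuration
#'
#' The GiaB `ExactMatchID` grammar distinguishing discovery from
#' refinement-only short-read labels is not standardised; the token rules are
#' therefore exposed here.
#'
#' @param sr_token token marking a short-read (Illumina) callset id.
#' @param refine_regex regex marking refinement-only callset ids; ids matching
#'   it never count as short-read discovery.
#' @export
discovery_config <- function(sr_token = "Ill", refine_regex = "refine") {
  list(sr_token = sr_token, refine_regex = refine_regex)
}

#' Classify the discovery technology of insertion records
#'
#' Partitions records into `short_read` vs `other` according to the
#' convention's INFO annotation. Chaisson-style callsets use the `UNION`
#' INFO variable (`Illumina` means short-read; `Pacbio` / `Bionano` mean
#' other). GiaB-style callsets use the `ExactMatchID` INFO tag: a record is
#' short-read when at least one comma-separated callset id carries the
#' short-read token as a discovery (not refinement-only) label. Records with
#' the tag missing are classified `other` and counted in the
#' `n_missing_tag` attribute.
#'
#' @param cs an `inschar_callset` (or a records data.frame plus `convention`).
#' @param convention overrides the callset convention if given.
#' @param cfg a [discovery_config()].
#' @return factor vector (levels `short_read`, `other`), one per record, with
#'   attribute `n_missing_tag`.
#' @export
parse_discovery_technology <- function(cs, convention = NULL, cfg = discovery_config()) {
  if (inherits(cs, "inschar_callset")) {
    records <- cs$records
    if (is.null(convention)) convention <- cs$convention
  } else {
    records <- cs
    if (is.null(convention)) convention <- "generic"
  }
  n <- nrow(records)
  out <- rep("other", n)
  missing_tag <- 0L
  if (convention == "chaisson") {
    v <- .info_tag(records$info, "UNION")
    missing_tag <- sum(is.na(v))
    out[!is.na(v) & v == "Illumina"] <- "short_read"
  } else if (convention == "giab") {
    v <- .info_tag(records$info, "ExactMatchID")
    missing_tag <- sum(is.na(v))
    sr <- vapply(v, function(x) {
      if (is.na(x)) return(FALSE)
      ids <- strsplit(x, ",", fixed = TRUE)[[1]]
      disc <- ids[!grepl(cfg$refine_regex, ids, ignore.case = TRUE)]
      any(grepl(paste0("(^|_)", cfg$sr_token), disc))
    }, logical(1), USE.NAMES = FALSE)
    out[sr] <- "short_read"
  } else {
    v <- .info_tag(records$info, "TECH")
    missing_tag <- sum(is.na(v))
    out[!is.na(v) & v %in% c("short_read", "Illumina", "SR")] <- "short_read"
  }
  res <- factor(out, levels = c("short_read", "other"))
  attr(res, "n_missing_tag") <- missing_tag
  res
}

#' Write a callset to a VCF file
#'
#' Writes VCF 4.2 with one body line per record; resolved insertions are
#' written as REF = anchor base (taken from `genome` when provided, else "N"),
#' ALT = REF + inserted sequence; unresolved records as symbolic `<INS>`.
#' Round-tripping through [read_vcf_insertions()] reproduces position,
#' inserted sequence, FILTER and genotype for every record.
#'
#' @param cs an `inschar_callset`.
#' @param path output path.
#' @param genome optional genome used to fill REF anchor bases.
#' @param sample sample column name.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(cs, path, genome = NULL, sample = "SAMPLE") {
  stopifnot(inherits(cs, "inschar_callset"))
  r <- cs$records
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=inschar",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=SCENARIO,Number=1,Type=String,Description=\"Simulation scenario\">",
    "##INFO=<ID=PARAM,Number=1,Type=String,Description=\"Scenario parameter\">",
    "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"Designed insertion type\">",
    "##INFO=<ID=EXPHOM,Number=1,Type=Integer,Description=\"Designed junctional homology (bp)\">",
    "##INFO=<ID=CONTEXT,Number=1,Type=String,Description=\"Designed site context\">",
    "##INFO=<ID=UNION,Number=1,Type=String,Description=\"Discovery technology\">",
    "##INFO=<ID=ExactMatchID,Number=1,Type=String,Description=\"Supporting callset ids\">",
    "##INFO=<ID=PARENTS,Number=1,Type=String,Description=\"Parental support\">",
    "##ALT=<ID=INS,Description=\"Insertion\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample)
  )
  lines <- character(nrow(r))
  if (nrow(r)) {
    for (i in seq_len(nrow(r))) {
      anchor <- "N"
      if (!is.null(genome)) {
        anchor <- substr(.chrom_seq(genome, r$chrom[i]), r$pos[i], r$pos[i])
      }
      if (r$resolved[i]) {
        ref <- anchor; alt <- paste0(anchor, r$inserted_seq[i])
      } else {
        ref <- anchor; alt <- "<INS>"
      }
      info <- if (is.na(r$info[i]) || r$info[i] == "") "." else r$info[i]
      gt <- if (is.na(r$genotype[i]) || r$genotype[i] == "") "." else r$genotype[i]
      filt <- if (is.na(r$filter[i]) || r$filter[i] == "") "." else r$filter[i]
      lines[i] <- paste(r$chrom[i], r$pos[i], r$record_id[i], ref, alt, ".",
                        filt, info, "GT", gt, sep = "\t")
    }
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(hdr, lines), con)
  invisible(path)
}
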